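# Synthetic DCE phantoms with known ground-truth ETM maps.

#' Phantom specification
#'
#' Describes one synthetic lesion: grid and voxel geometry, an ellipsoidal
#' tumor, the spatial statistics of the ground-truth K-trans field, uniform
#' ve / vp, and the signal noise level. The K-trans field is a correlated
#' Gaussian random field (smoothed white noise) standardised to the
#' requested tumor mean/SD and clipped to the physiologic box \[0, 5\]
#' 1/min. A `core` entry (list with `radius_frac` and `ktrans_factor`)
#' optionally multiplies K-trans inside a concentric core, emulating a
#' poorly-perfused / necrotic center.
#'
#' @param grid_shape integer `c(nx, ny, nz)` voxels.
#' @param voxel_size mm per axis, length 3 (slices may be thicker,
#'   e.g. `c(2, 2, 5)`).
#' @param center tumor center in voxel coordinates (defaults to the grid
#'   center).
#' @param radii ellipsoid semi-axes, mm.
#' @param ktrans_mean,ktrans_spatial_sd tumor K-trans mean and spatial SD,
#'   1/min.
#' @param ktrans_correlation_length Gaussian correlation length, mm.
#' @param ve_mean,vp_mean uniform tumor volume fractions.
#' @param ktrans_background,ve_background,vp_background values outside the
#'   tumor.
#' @param noise_sd additive Gaussian noise SD on the magnitude signal
#'   (signal units; the default M0 is 1000).
#' @param rician if `TRUE`, Rician instead of additive Gaussian noise.
#' @param core optional list(`radius_frac`, `ktrans_factor`).
#' @param T10,M0 signal-model constants for this lesion.
#' @param seed integer seed making the phantom reproducible (drives the
#'   session-specific field component and the noise).
#' @param field_seed optional separate seed for the lesion's underlying
#'   vascular pattern. Paired pre/post phantoms of one lesion share
#'   `field_seed` (vasculature persists between sessions) while their
#'   `seed` differs.
#' @param session_weight fraction (0-1) of the K-trans field variance that
#'   is session-specific when `field_seed` is set: the field is
#'   `sqrt(1-w^2) * base + w * session`, modelling mild vascular
#'   remodelling between imaging sessions.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape = c(16, 16, 8),
                         voxel_size = c(2, 2, 5),
                         center = (grid_shape + 1) / 2,
                         radii = c(8, 8, 8),
                         ktrans_mean = 0.25,
                         ktrans_spatial_sd = 0.12,
                         ktrans_correlation_length = 3,
                         ve_mean = 0.3, vp_mean = 0.03,
                         ktrans_background = 0.01,
                         ve_background = 0.2, vp_background = 0.01,
                         noise_sd = 0, rician = FALSE,
                         core = NULL,
                         T10 = 1.0, M0 = 1000,
                         seed = 1L, field_seed = NULL,
                         session_weight = 0.2) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1),
            length(voxel_size) == 3, all(voxel_size > 0),
            all(radii > 0),
            ktrans_mean >= 0, ktrans_mean <= 5, ktrans_spatial_sd >= 0,
            ve_mean > 0, ve_mean <= 1, vp_mean >= 0, vp_mean <= 1,
            noise_sd >= 0, session_weight >= 0, session_weight <= 1)
  # tumor must fit inside the grid
  ext_mm <- grid_shape * voxel_size
  c_mm <- (center - 0.5) * voxel_size
  if (any(c_mm - radii < 0) || any(c_mm + radii > ext_mm))
    stop("tumor ellipsoid does not fit inside the grid")
  if (!is.null(core))
    stopifnot(core$radius_frac > 0, core$radius_frac < 1,
              core$ktrans_factor >= 0)
  structure(as.list(environment()), class = "phantom_spec")
}

# Correlated Gaussian random field: white noise smoothed with a separable
# Gaussian kernel (sigma in voxels per axis), reflect padding.
gaussian_random_field <- function(grid_shape, sigma_vox) {
  x <- array(rnorm(prod(grid_shape)), grid_shape)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    kern <- dnorm(seq(-r, r), sd = s)
    kern <- kern / sum(kern)
    x <- apply_along(x, ax, function(v) conv_reflect(v, kern))
  }
  x
}

# convolve vector with symmetric kernel, reflected edges
conv_reflect <- function(v, kern) {
  r <- (length(kern) - 1L) / 2L
  n <- length(v)
  q <- (1 - r):(n + r)
  m <- (q - 1) %% (2 * n)
  m <- ifelse(m < n, m + 1, 2 * n - m)
  vp <- v[m]
  as.numeric(stats::filter(vp, kern, sides = 2))[r + seq_len(n)]
}

apply_along <- function(x, ax, f) {
  d <- dim(x)
  perm <- c(ax, setdiff(1:3, ax))
  y <- aperm(x, perm)
  m <- matrix(y, nrow = d[ax])
  m <- apply(m, 2, f)
  y <- array(m, d[perm])
  aperm(y, order(perm))
}

#' Ellipsoid tumor mask for a phantom spec
#' @param spec a [phantom_spec()].
#' @return Logical 3D array.
#' @export
phantom_mask <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  co <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3]))
  dx <- (co$i - spec$center[1]) * spec$voxel_size[1] / spec$radii[1]
  dy <- (co$j - spec$center[2]) * spec$voxel_size[2] / spec$radii[2]
  dz <- (co$k - spec$center[3]) * spec$voxel_size[3] / spec$radii[3]
  array(dx^2 + dy^2 + dz^2 <= 1, d)
}

#' Generate a synthetic DCE phantom
#'
#' Builds ground-truth ETM parameter maps (heterogeneous K-trans, uniform
#' ve and vp inside an ellipsoidal tumor, background values elsewhere),
#' synthesises the 4D dynamic SPGR signal through [forward_etm()] and
#' [concentration_to_signal()], and adds noise. Bit-reproducible for a
#' fixed spec (the spec's `seed` drives all randomness).
#'
#' @param spec a [phantom_spec()].
#' @param protocol a [acquisition_protocol()].
#' @param aif an [aif_curve()]; default [generate_aif()] of `protocol`.
#' @param maps_only if `TRUE`, skip signal synthesis (ground-truth maps and
#'   mask only) — the fluid-model stages only need the maps.
#' @return A `dce_phantom`: `signal` (4D array or NULL), `mask`,
#'   `truth` (list of 3D arrays `ktrans`, `ve`, `vp`), `aif`, `protocol`,
#'   `spec`, `affine` (diagonal voxel-size affine, mm).
#' @export
generate_phantom <- function(spec, protocol = acquisition_protocol(),
                             aif = generate_aif(protocol),
                             maps_only = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  mask <- phantom_mask(spec)
  if (!any(mask)) stop("degenerate geometry: tumor mask is empty")
  set.seed(spec$seed)

  kt <- array(spec$ktrans_background, d)
  if (spec$ktrans_spatial_sd > 0) {
    sig_vox <- spec$ktrans_correlation_length / spec$voxel_size
    if (!is.null(spec$field_seed)) {
      set.seed(spec$field_seed)
      g <- gaussian_random_field(d, sig_vox)
      w <- spec$session_weight
      if (w > 0) {
        set.seed(spec$seed)
        g <- sqrt(1 - w^2) * g + w * gaussian_random_field(d, sig_vox)
      }
    } else {
      g <- gaussian_random_field(d, sig_vox)
    }
    gt <- g[mask]
    gt <- (gt - mean(gt)) / max(sd(gt), 1e-12)
    kt[mask] <- spec$ktrans_mean + spec$ktrans_spatial_sd * gt
  } else {
    kt[mask] <- spec$ktrans_mean
  }
  if (!is.null(spec$core)) {
    cmask <- phantom_mask(within_spec_core(spec))
    kt[cmask & mask] <- kt[cmask & mask] * spec$core$ktrans_factor
  }
  kt <- pmin(pmax(kt, 0), 5)
  ve <- array(spec$ve_background, d); ve[mask] <- spec$ve_mean
  vp <- array(spec$vp_background, d); vp[mask] <- spec$vp_mean

  signal <- NULL
  if (!maps_only) {
    conc <- forward_etm_batch(as.vector(kt), as.vector(ve), as.vector(vp), aif)
    sig <- concentration_to_signal(conc, protocol, T10 = spec$T10, M0 = spec$M0)
    if (spec$noise_sd > 0) {
      if (isTRUE(spec$rician)) {
        n1 <- rnorm(length(sig), sd = spec$noise_sd)
        n2 <- rnorm(length(sig), sd = spec$noise_sd)
        sig <- sqrt((sig + n1)^2 + n2^2)
      } else {
        sig <- sig + rnorm(length(sig), sd = spec$noise_sd)
      }
    }
    signal <- array(sig, c(d, protocol$n_total_phases))
  }
  structure(list(signal = signal, mask = mask,
                 truth = list(ktrans = kt, ve = ve, vp = vp),
                 aif = aif, protocol = protocol, spec = spec,
                 affine = diag(c(spec$voxel_size, 1))),
            class = "dce_phantom")
}

within_spec_core <- function(spec) {
  s <- spec
  s$radii <- spec$radii * spec$core$radius_frac
  s
}

#' @export
print.dce_phantom <- function(x, ...) {
  cat(sprintf("DCE phantom: grid %s, %d tumor voxels, noise SD %g\n",
              paste(x$spec$grid_shape, collapse = "x"), sum(x$mask),
              x$spec$noise_sd))
  invisible(x)
}
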