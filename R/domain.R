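# Simulation domain for the steady-state interstitial fluid model.

#' Tissue physical parameters for the fluid model
#'
#' One parameter set per tissue class. Defaults are the brain-tumor values
#' used throughout the package: interstitial hydraulic conductivity
#' `K_H` (m^2/(Pa s)) 5.65e-15 (normal) / 4.9e-13 (tumor), vascular
#' hydraulic conductivity `L_p` 8e-14 / 6.4e-13, vessel exchange area
#' `S/V` (1/m) 10000 / 20000, and effective (lumped Starling) pressure
#' `P_eff` (Pa) 400 / 1550. The lymphatic clearance term is identically
#' zero (no lymphatics in brain), so it is not a parameter.
#'
#' @param normal,tumor named lists with `K_H`, `L_p`, `S_over_V`, `P_eff`.
#' @return A `tissue_properties` object.
#' @export
tissue_properties <- function(normal = list(K_H = 5.65e-15, L_p = 8e-14,
                                            S_over_V = 1e4, P_eff = 400),
                              tumor = list(K_H = 4.9e-13, L_p = 6.4e-13,
                                           S_over_V = 2e4, P_eff = 1550)) {
  chk <- function(p) stopifnot(p$K_H > 0, p$L_p > 0, p$S_over_V > 0,
                               p$P_eff >= 0)
  chk(normal); chk(tumor)
  structure(list(normal = normal, tumor = tumor),
            class = "tissue_properties")
}

new_domain <- function(dims, spacing, tissue, boundary, boundary_value,
                       origin_mm = c(0, 0, 0), ratio = NULL) {
  structure(list(dims = as.integer(dims), spacing = spacing,
                 tissue = tissue, boundary = boundary,
                 boundary_value = boundary_value, origin_mm = origin_mm,
                 ratio = ratio),
            class = "ifp_domain")
}

#' Build an isotropic simulation domain from a tumor mask
#'
#' Reslices a (possibly anisotropic) tumor mask to an isotropic grid by
#' nearest-neighbour sampling and pads it with normal tissue by `margin`
#' mm on every side. The pressure boundary condition (Dirichlet, default
#' 0 Pa, i.e. normal-brain far-field) is imposed on the outermost voxel
#' shell of the padded box.
#'
#' @param mask 3D array (logical or 0/1) marking tumor voxels.
#' @param voxel_size source voxel size, mm per axis (length 3), e.g. taken
#'   from the NIfTI affine.
#' @param target_spacing isotropic target spacing, mm (default 1).
#' @param margin normal-tissue padding around the tumor bounding box, mm
#'   (default 20); must be at least 2 target voxels.
#' @param boundary_pressure Dirichlet value at the domain boundary, Pa.
#' @return An `ifp_domain` (without the K-trans ratio field; see
#'   [make_ktrans_ratio()]).
#' @export
build_domain <- function(mask, voxel_size, target_spacing = 1, margin = 20,
                         boundary_pressure = 0) {
  mask <- array(as.logical(mask), dim(mask))
  stopifnot(length(dim(mask)) == 3, length(voxel_size) == 3,
            all(voxel_size > 0), target_spacing > 0)
  if (!any(mask)) stop("empty tumor mask")
  if (margin < 2 * target_spacing)
    stop("margin must be at least 2 target voxels (", 2 * target_spacing,
         " mm)")
  idx <- which(mask, arr.ind = TRUE)
  # tumor bounding box in source mm (voxel centers at (i-0.5)*vox)
  lo_mm <- (apply(idx, 2, min) - 1) * voxel_size
  hi_mm <- apply(idx, 2, max) * voxel_size
  lo <- lo_mm - margin
  hi <- hi_mm + margin
  dims <- pmax(ceiling((hi - lo) / target_spacing), 3L)
  tissue <- array(0L, dims)
  ax <- lapply(1:3, function(a) lo[a] + (seq_len(dims[a]) - 0.5) * target_spacing)
  # nearest-neighbour source lookup per target voxel
  src <- lapply(1:3, function(a) {
    i <- floor(ax[[a]] / voxel_size[a]) + 1L
    ifelse(i >= 1 & i <= dim(mask)[a], i, NA_integer_)
  })
  gi <- expand.grid(i = src[[1]], j = src[[2]], k = src[[3]])
  inside <- !is.na(gi$i) & !is.na(gi$j) & !is.na(gi$k)
  lin <- gi$i[inside] + (gi$j[inside] - 1L) * dim(mask)[1] +
    (gi$k[inside] - 1L) * prod(dim(mask)[1:2])
  tv <- logical(prod(dims))
  tv[inside] <- mask[lin]
  tissue[array(tv, dims)] <- 1L
  boundary <- array(FALSE, dims)
  boundary[c(1, dims[1]), , ] <- TRUE
  boundary[, c(1, dims[2]), ] <- TRUE
  boundary[, , c(1, dims[3])] <- TRUE
  if (any(tissue == 1L & boundary))
    stop("tumor touches the domain boundary; increase margin")
  new_domain(dims, target_spacing, tissue, boundary, boundary_pressure,
             origin_mm = lo)
}

#' Spherical-boundary domain with a centered spherical tumor
#'
#' Convenience constructor for benchmark problems: a spherical tumor of
#' radius `tumor_radius` mm at the center, normal tissue out to
#' `tumor_radius + margin` mm, and the Dirichlet boundary imposed on all
#' voxels beyond that radius, so the discrete problem matches the
#' spherically symmetric reference solution ([radial_reference_ifp()])
#' exactly in geometry.
#'
#' @param tumor_radius tumor radius, mm.
#' @param margin normal-tissue thickness, mm.
#' @param spacing isotropic spacing, mm.
#' @param boundary_pressure Dirichlet value, Pa.
#' @param cube_boundary if `TRUE` put the boundary on the box faces
#'   instead of the sphere `r = tumor_radius + margin`.
#' @return An `ifp_domain`.
#' @export
spherical_domain <- function(tumor_radius, margin = 20, spacing = 1,
                             boundary_pressure = 0, cube_boundary = FALSE) {
  stopifnot(tumor_radius > 0, margin >= 2 * spacing, spacing > 0)
  R <- tumor_radius + margin
  n <- 2L * ceiling(R / spacing) + 1L
  dims <- c(n, n, n)
  ctr <- (n + 1) / 2
  g <- (seq_len(n) - ctr) * spacing
  r2 <- outer(outer(g^2, g^2, "+"), g^2, "+")
  r <- sqrt(r2)
  tissue <- array(0L, dims)
  tissue[r <= tumor_radius] <- 1L
  if (cube_boundary) {
    boundary <- array(FALSE, dims)
    boundary[c(1, n), , ] <- TRUE
    boundary[, c(1, n), ] <- TRUE
    boundary[, , c(1, n)] <- TRUE
  } else {
    boundary <- array(r > R, dims)
  }
  dom <- new_domain(dims, spacing, tissue, boundary, boundary_pressure,
                    origin_mm = rep((0.5 - ctr) * spacing, 3))
  dom$radius_mm <- r
  # exact geometry: lets the assembler use embedded-interface corrections
  dom$geometry <- list(type = "sphere", tumor_radius = tumor_radius,
                       outer_radius = if (cube_boundary) NA_real_ else R,
                       center_vox = c(ctr, ctr, ctr))
  dom
}

#' Attach the K-trans modulation ratio field to a domain
#'
#' Resamples a K-trans map (on its own grid) to the domain grid by
#' trilinear interpolation and normalises it by its mean over tumor
#' voxels: the ratio field is `Ktrans / <Ktrans>` inside the tumor and 1
#' in normal tissue, so its tumor mean is 1 by construction. This is the
#' dimensionless factor that modulates the transvascular source to account
#' for heterogeneous fluid leakiness.
#'
#' @param ktrans 3D K-trans array (1/min).
#' @param voxel_size K-trans voxel size, mm per axis.
#' @param domain an `ifp_domain` from [build_domain()].
#' @param origin_mm position (mm, in the K-trans frame) of the corner of
#'   the K-trans grid; defaults to `c(0,0,0)` (shared frame with the mask
#'   the domain was built from).
#' @return The domain with `$ratio` set.
#' @export
make_ktrans_ratio <- function(ktrans, voxel_size, domain,
                              origin_mm = c(0, 0, 0)) {
  stopifnot(inherits(domain, "ifp_domain"), length(dim(ktrans)) == 3,
            length(voxel_size) == 3)
  dims <- domain$dims
  ax <- lapply(1:3, function(a)
    domain$origin_mm[a] + (seq_len(dims[a]) - 0.5) * domain$spacing)
  kt <- trilinear_sample(ktrans, voxel_size, ax, origin_mm)
  ratio <- array(1, dims)
  tum <- domain$tissue == 1L
  mk <- mean(kt[tum])
  if (!is.finite(mk) || mk <= 0)
    stop("tumor-mean K-trans is zero; cannot form the modulation ratio")
  ratio[tum] <- kt[tum] / mk
  # renormalise exactly (interpolation keeps this at 1 up to rounding)
  ratio[tum] <- ratio[tum] / mean(ratio[tum])
  domain$ratio <- ratio
  domain
}

# trilinear sampling of a 3D array (voxel centers at (i-0.5)*vox + origin)
# at the tensor grid ax (list of 3 coordinate vectors, mm); clamped edges
trilinear_sample <- function(arr, voxel_size, ax, origin_mm = c(0, 0, 0)) {
  d <- dim(arr)
  fr <- list(); i0 <- list()
  for (a in 1:3) {
    x <- (ax[[a]] - origin_mm[a]) / voxel_size[a] - 0.5 # 0-based cell coord
    x <- pmin(pmax(x, 0), d[a] - 1)
    i <- pmin(floor(x), d[a] - 2); i[d[a] == 1] <- 0
    fr[[a]] <- x - i
    i0[[a]] <- as.integer(i) + 1L
  }
  nx <- length(ax[[1]]); ny <- length(ax[[2]]); nz <- length(ax[[3]])
  out <- array(0, c(nx, ny, nz))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    wi <- if (dx == 0) 1 - fr[[1]] else fr[[1]]
    wj <- if (dy == 0) 1 - fr[[2]] else fr[[2]]
    wk <- if (dz == 0) 1 - fr[[3]] else fr[[3]]
    ii <- pmin(i0[[1]] + dx, d[1]); jj <- pmin(i0[[2]] + dy, d[2])
    kk <- pmin(i0[[3]] + dz, d[3])
    w <- outer(outer(wi, wj), wk)
    out <- out + w * arr[ii, jj, kk, drop = FALSE]
  }
  out
}

#' @export
print.ifp_domain <- function(x, ...) {
  cat(sprintf("IFP domain: %s voxels @ %g mm, %d tumor voxels%s\n",
              paste(x$dims, collapse = "x"), x$spacing, sum(x$tissue == 1L),
              if (is.null(x$ratio)) " (no ratio field)" else ""))
  invisible(x)
}
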