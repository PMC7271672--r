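# Extended Tofts model (ETM):
#   C_t(t) = Ktrans * int_0^t exp(-kep (t - tau)) C_p(tau) dtau + vp C_p(t)
# with kep = Ktrans / ve.  Ktrans, kep are in 1/min; the time grid is in
# seconds, so rates are converted to 1/s where they meet time.

# Convolution of exp(-k s) with the piecewise-linear interpolant of cp on
# the sample grid, evaluated at the grid points.  Exact per interval:
#   I_i = e^{-k dt} I_{i-1} + cp_i J0 + (cp_{i-1} - cp_i) J1 / dt
#   J0 = (1 - e^{-k dt})/k,  J1 = (1 - e^{-k dt}(1 + k dt))/k^2
# `k` may be a vector (one rate per voxel); returns length(k) x length(t).
exp_conv <- function(k, times, cp) {
  nt <- length(times)
  nk <- length(k)
  out <- matrix(0, nk, nt)
  if (nt < 2) return(out)
  acc <- numeric(nk)
  for (i in 2:nt) {
    dt <- times[i] - times[i - 1]
    x <- k * dt
    E <- exp(-x)
    small <- x < 1e-6
    J0 <- ifelse(small, dt * (1 - x / 2), (1 - E) / k)
    J1 <- ifelse(small, dt^2 * (0.5 - x / 3), (1 - E * (1 + x)) / k^2)
    acc <- E * acc + cp[i] * J0 + (cp[i - 1] - cp[i]) * J1 / dt
    out[, i] <- acc
  }
  out
}

#' Forward extended Tofts model
#'
#' Tissue contrast concentration predicted by the two-compartment extended
#' Tofts model,
#' \deqn{C_t(t) = K^{trans} \int_0^t e^{-k_{ep}(t-\tau)} C_p(\tau)\,d\tau
#'   + v_p C_p(t),}
#' with backflux rate \eqn{k_{ep} = K^{trans}/v_e}. The convolution is
#' evaluated exactly for the piecewise-linear interpolant of the AIF on the
#' acquisition time grid, so the forward model is deterministic and
#' consistent with [fit_etm_voxel()].
#'
#' @param ktrans volume transfer constant, 1/min, in \[0, 5\].
#' @param ve extravascular extracellular volume fraction, in (0, 1\] when
#'   `ktrans > 0`.
#' @param vp plasma volume fraction, in \[0, 1\].
#' @param aif an [aif_curve()].
#' @return Tissue concentration (mM) on `aif$times`.
#' @export
forward_etm <- function(ktrans, ve, vp, aif) {
  stopifnot(inherits(aif, "aif_curve"),
            ktrans >= 0, ktrans <= 5, vp >= 0, vp <= 1, ve >= 0, ve <= 1)
  if (ktrans > 0 && ve <= 0)
    stop("ve = 0 with ktrans > 0: kep = ktrans/ve is undefined")
  kep_s <- if (ktrans > 0) (ktrans / ve) / 60 else 0
  conv <- drop(exp_conv(kep_s, aif$times, aif$cp))
  (ktrans / 60) * conv + vp * aif$cp
}

# Batch forward model used by the phantom generator: ktrans/ve/vp vectors,
# one tissue curve per row.
forward_etm_batch <- function(ktrans, ve, vp, aif) {
  kep_s <- ifelse(ktrans > 0, (ktrans / pmax(ve, 1e-12)) / 60, 0)
  conv <- exp_conv(kep_s, aif$times, aif$cp)
  (ktrans / 60) * conv + outer(vp, aif$cp)
}

#' Extract an AIF from a voxel of a concentration volume
#'
#' Takes the blood concentration time course at the given voxel (the
#' conventional choice is a sagittal-sinus voxel) and converts whole-blood
#' to plasma concentration with the hematocrit correction
#' `C_p = C_b / (1 - Hct)`.
#'
#' @param conc a `conc_volume` from [signal_to_concentration()] with a 4D
#'   `conc` array.
#' @param voxel_index integer vector `c(i, j, k)`.
#' @param hematocrit hematocrit fraction in \[0, 1); default 0.45.
#' @return An [aif_curve()].
#' @export
extract_aif <- function(conc, voxel_index, hematocrit = 0.45) {
  stopifnot(inherits(conc, "conc_volume"),
            length(voxel_index) == 3,
            hematocrit >= 0, hematocrit < 1)
  dims <- dim(conc$conc)
  stopifnot(length(dims) == 4, all(voxel_index >= 1),
            all(voxel_index <= dims[1:3]))
  cb <- conc$conc[voxel_index[1], voxel_index[2], voxel_index[3], ]
  cb[is.na(cb)] <- 0
  if (all(cb == 0)) stop("all-zero voxel curve: not a usable AIF")
  aif_curve(conc$times, cb / (1 - hematocrit))
}

#' Fit the extended Tofts model to one voxel
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt, via
#' \pkg{minpack.lm}) minimising the sum of squared errors between the
#' measured concentration curve and [forward_etm()]. Parameter bounds are
#' \eqn{K^{trans} \in [0,5]} 1/min and \eqn{v_e, v_p \in [0,1]}; `ve` has a
#' small positive lower bound so that \eqn{k_{ep}} stays defined during the
#' search.
#'
#' @param curve measured tissue concentration (mM) on the AIF time grid;
#'   `NA` samples are dropped from the objective.
#' @param aif an [aif_curve()].
#' @param init starting values `c(ktrans, ve, vp)`; default
#'   `c(0.1, 0.2, 0.05)`.
#' @param lower,upper bound box, default `c(0, 1e-3, 0)` and `c(5, 1, 1)`.
#' @param multistart if `TRUE`, also start from two further points spread
#'   over the box and keep the best fit.
#' @return List: `ktrans`, `ve`, `vp`, `kep` (1/min), `sse`, `fit_success`.
#'   Non-convergence returns `fit_success = FALSE` with `sse = Inf`.
#' @export
fit_etm_voxel <- function(curve, aif, init = c(0.1, 0.2, 0.05),
                          lower = c(0, 1e-3, 0), upper = c(5, 1, 1),
                          multistart = FALSE) {
  stopifnot(inherits(aif, "aif_curve"), length(curve) == length(aif$times))
  ok <- is.finite(curve)
  if (sum(ok) < 4) {
    return(list(ktrans = NA_real_, ve = NA_real_, vp = NA_real_,
                kep = NA_real_, sse = Inf, fit_success = FALSE))
  }
  resid_fn <- function(par) {
    kep_s <- (par[1] / par[2]) / 60
    pred <- (par[1] / 60) * drop(exp_conv(kep_s, aif$times, aif$cp)) +
      par[3] * aif$cp
    pred[ok] - curve[ok]
  }
  starts <- list(init)
  if (multistart)
    starts <- c(starts, list(c(0.5, 0.5, 0.02), c(0.02, 0.1, 0.1)))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = pmin(pmax(st, lower), upper), fn = resid_fn,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse)
      best <- list(par = fit$par, sse = sse)
  }
  if (is.null(best)) {
    return(list(ktrans = NA_real_, ve = NA_real_, vp = NA_real_,
                kep = NA_real_, sse = Inf, fit_success = FALSE))
  }
  p <- pmin(pmax(best$par, lower), upper)
  list(ktrans = p[1], ve = p[2], vp = p[3],
       kep = p[1] / p[2], sse = best$sse, fit_success = TRUE)
}

#' Fit the extended Tofts model voxelwise over a masked volume
#'
#' Applies [fit_etm_voxel()] to every voxel inside the mask. Voxels whose
#' fit fails are flagged in `fit_success` and carry `NA` parameters; their
#' count is reported via a message so heavily corrupted volumes are
#' noticed.
#'
#' @param conc a `conc_volume` with a 4D `conc` array, or a plain 4D array.
#' @param aif an [aif_curve()].
#' @param mask logical/0-1 3D array selecting voxels to fit; must be
#'   non-empty.
#' @param ... passed to [fit_etm_voxel()].
#' @return An `etm_maps` object: 3D arrays `ktrans`, `ve`, `vp`, `kep`,
#'   `sse`, logical `fit_success`, plus `n_failed`.
#' @export
fit_etm_volume <- function(conc, aif, mask, ...) {
  arr <- if (inherits(conc, "conc_volume")) conc$conc else conc
  stopifnot(length(dim(arr)) == 4, inherits(aif, "aif_curve"))
  mask <- array(as.logical(mask), dim = dim(arr)[1:3])
  if (!any(mask)) stop("empty mask")
  dims <- dim(arr)[1:3]
  mk <- function() array(NA_real_, dims)
  maps <- list(ktrans = mk(), ve = mk(), vp = mk(), kep = mk(), sse = mk(),
               fit_success = array(FALSE, dims))
  idx <- which(mask)
  cmat <- matrix(arr, ncol = dim(arr)[4])
  for (v in idx) {
    f <- fit_etm_voxel(cmat[v, ], aif, ...)
    maps$ktrans[v] <- f$ktrans; maps$ve[v] <- f$ve; maps$vp[v] <- f$vp
    maps$kep[v] <- f$kep; maps$sse[v] <- f$sse
    maps$fit_success[v] <- f$fit_success
  }
  maps$n_failed <- sum(!maps$fit_success[idx])
  if (maps$n_failed > 0)
    message(maps$n_failed, " of ", length(idx), " voxel fits failed")
  class(maps) <- "etm_maps"
  maps
}

#' @export
print.etm_maps <- function(x, ...) {
  ok <- x$fit_success
  cat(sprintf("ETM maps: %d fitted voxels (%d failed); median Ktrans %.3f /min\n",
              sum(ok), x$n_failed, median(x$ktrans[ok], na.rm = TRUE)))
  invisible(x)
}
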