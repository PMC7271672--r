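# Spoiled-gradient-echo steady-state signal model and its exact inverse.
# S = M0 sin(a) (1 - E1) / (1 - cos(a) E1),  E1 = exp(-TR * R1),
# R1(t) = 1/T10 + r1 * C(t).

spgr_signal <- function(R1, M0, TR, flip_deg) {
  a <- flip_deg * pi / 180
  E1 <- exp(-TR * R1)
  M0 * sin(a) * (1 - E1) / (1 - cos(a) * E1)
}

#' Convert a concentration time course to SPGR signal
#'
#' Forward SPGR model: the tissue longitudinal relaxation rate is
#' `R1(t) = 1/T10 + r1 C(t)` and the steady-state spoiled gradient-echo
#' signal is evaluated at the protocol's TR and flip angle. Deterministic;
#' noise is added by the phantom generator, not here.
#'
#' @param conc concentration time course (mM); vector, or matrix with one
#'   row per voxel and one column per phase.
#' @param protocol a [acquisition_protocol()] object.
#' @param T10 native T1, seconds (defaults to the protocol value).
#' @param M0 equilibrium signal scale.
#' @return Signal in the same shape as `conc`.
#' @export
concentration_to_signal <- function(conc, protocol, T10 = protocol$T10_default,
                                    M0 = 1000) {
  stopifnot(inherits(protocol, "dce_protocol"), T10 > 0)
  R1 <- 1 / T10 + protocol$relaxivity_r1 * conc
  out <- spgr_signal(R1, M0, protocol$repetition_time, protocol$flip_angle)
  dim(out) <- dim(conc)
  out
}

#' Convert DCE signal to contrast concentration
#'
#' Exact inversion of the SPGR steady-state equation. The baseline signal
#' `S0` is the mean over the pre-injection phases; together with the
#' assumed `T10` it fixes the unknown scale `M0 sin(a)`, after which
#' `E1 = exp(-TR R1)` has the closed form
#' `E1 = (1 - rho) / (1 - cos(a) rho)` with
#' `rho = (S / S0) * (1 - E10) / (1 - cos(a) E10)`.
#' Then `dR1 = R1 - 1/T10` and `C = dR1 / r1`, clipped below at
#' `conc_floor`. Voxels/phases where the inversion argument leaves (0, 1)
#' (non-physical signal, e.g. extreme noise) are flagged: their
#' concentration is set to `NA` and counted.
#'
#' @param signal numeric vector (one voxel) or matrix (voxels x phases) or
#'   4D array (x,y,z,t) of dynamic signal.
#' @param protocol a [acquisition_protocol()] object.
#' @param T10 assumed native T1, seconds.
#' @param conc_floor lower clip for concentration, mM (default 0).
#' @return List of class `conc_volume`: `conc` (same shape as `signal`),
#'   `dR1` (1/s), `times` (s), `n_flagged` (count of non-invertible
#'   samples).
#' @export
signal_to_concentration <- function(signal, protocol,
                                    T10 = protocol$T10_default,
                                    conc_floor = 0) {
  stopifnot(inherits(protocol, "dce_protocol"), T10 > 0)
  dims <- dim(signal)
  nt <- protocol$n_total_phases
  if (is.null(dims)) {
    smat <- matrix(signal, nrow = 1)
  } else if (length(dims) == 2) {
    smat <- signal
  } else if (length(dims) == 4) {
    stopifnot(dims[4] == nt)
    smat <- matrix(signal, ncol = nt)
  } else stop("signal must be a vector, matrix or 4D array")
  if (ncol(smat) != nt) stop("signal has ", ncol(smat),
                             " phases but protocol expects ", nt)
  if (protocol$n_baseline_phases < 2)
    stop("need at least 2 baseline phases to estimate S0")

  ca <- cos(protocol$flip_angle * pi / 180)
  TR <- protocol$repetition_time
  E10 <- exp(-TR / T10)
  S0 <- rowMeans(smat[, seq_len(protocol$n_baseline_phases), drop = FALSE])
  f10 <- (1 - E10) / (1 - ca * E10)
  rho <- sweep(smat, 1, S0, "/") * f10
  E1 <- (1 - rho) / (1 - ca * rho)
  bad <- !is.finite(E1) | E1 <= 0 | E1 >= 1
  E1[bad] <- NA_real_
  R1 <- -log(E1) / TR
  dR1 <- R1 - 1 / T10
  conc <- dR1 / protocol$relaxivity_r1
  conc <- pmax(conc, conc_floor)
  conc[bad] <- NA_real_
  shape_back <- function(m) { if (!is.null(dims)) dim(m) <- dims else m <- drop(m); m }
  structure(list(conc = shape_back(conc),
                 dR1 = shape_back(dR1),
                 times = protocol_times(protocol),
                 n_flagged = sum(bad)),
            class = "conc_volume")
}
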