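#' Population bolus model for the arterial input function
#'
#' Continuous-time plasma concentration of a contrast bolus, modelled as a
#' difference of two exponentials (fast uptake, slower washout) scaled by
#' dose:
#' \deqn{C_p(t) = A\,\mathrm{dose}\,(e^{-m_1 (t-t_0)} - e^{-m_2 (t-t_0)}),\quad t \ge t_0,}
#' with \eqn{m_2 > m_1 \ge 0} so the curve rises from zero, peaks at
#' \eqn{t_0 + \log(m_2/m_1)/(m_2-m_1)} and decays bi-exponentially. A
#' measured sagittal-sinus AIF would normally drive the kinetic model; this
#' parametric population curve plays that role for synthetic data, where a
#' deterministic, differentiable ground truth is worth more than fidelity
#' to any one patient.
#'
#' Default rate constants (`m1` 0.008/s, `m2` 0.08/s) give a ~30 s rise,
#' slow enough to be resolved by a 5-6 s dynamic acquisition, and
#' `amplitude` is set so that a unit dose peaks near 5 mM, a typical plasma
#' peak for a standard weight-based gadolinium injection.
#'
#' @param t times, seconds (vector).
#' @param bolus_arrival arrival time \eqn{t_0}, seconds.
#' @param dose dimensionless dose scale (1 = standard injection).
#' @param amplitude scale A, mM.
#' @param m1,m2 washout and uptake rate constants, 1/s (`m2 > m1`).
#' @return Plasma concentration, mM, same length as `t`.
#' @seealso [generate_aif()] to sample it on a protocol time grid,
#'   [aif_peak()] for the closed-form maximum.
#' @export
aif_bolus <- function(t, bolus_arrival = 55, dose = 1, amplitude = 7.45,
                      m1 = 0.008, m2 = 0.08) {
  stopifnot(m2 > m1, m1 >= 0, dose >= 0, amplitude >= 0)
  tau <- t - bolus_arrival
  cp <- ifelse(tau > 0, amplitude * dose * (exp(-m1 * tau) - exp(-m2 * tau)), 0)
  cp
}

#' Closed-form peak of the bolus model
#'
#' @inheritParams aif_bolus
#' @return List with `time` (seconds) and `cp` (mM) at the maximum.
#' @export
aif_peak <- function(bolus_arrival = 55, dose = 1, amplitude = 7.45,
                     m1 = 0.008, m2 = 0.08) {
  stopifnot(m2 > m1, m1 > 0)
  tpk <- bolus_arrival + log(m2 / m1) / (m2 - m1)
  list(time = tpk,
       cp = aif_bolus(tpk, bolus_arrival, dose, amplitude, m1, m2))
}

#' Sample an arterial input function on the acquisition grid
#'
#' Evaluates the population bolus model at the protocol's dynamic-phase
#' times. The bolus must arrive no earlier than the end of the baseline
#' (pre-injection) phases and within the scan window.
#'
#' @param protocol a [acquisition_protocol()] object.
#' @param bolus_params named list overriding [aif_bolus()] parameters
#'   (`dose`, `amplitude`, `m1`, `m2`).
#' @param bolus_arrival bolus arrival time, seconds; the default is the
#'   first post-injection phase time, i.e. injection synchronized with the
#'   start of a dynamic phase, which also keeps the sampled curve an exact
#'   piecewise-linear representation at the bolus onset.
#' @return An `aif_curve`: list with `times` (s) and `cp` (mM).
#' @export
generate_aif <- function(protocol, bolus_params = list(),
                         bolus_arrival = NULL) {
  stopifnot(inherits(protocol, "dce_protocol"))
  times <- protocol_times(protocol)
  baseline_end <- times[protocol$n_baseline_phases]
  if (is.null(bolus_arrival))
    bolus_arrival <- times[protocol$n_baseline_phases + 1]
  if (bolus_arrival < baseline_end)
    stop("bolus_arrival precedes the end of the baseline phases")
  if (bolus_arrival > max(times))
    stop("bolus_arrival outside the scan window")
  args <- c(list(t = times, bolus_arrival = bolus_arrival), bolus_params)
  cp <- do.call(aif_bolus, args)
  stopifnot(all(is.finite(cp)), all(cp >= 0))
  aif_curve(times, cp)
}

#' Construct an AIF curve object
#'
#' @param times sample times, seconds, strictly increasing.
#' @param cp plasma concentration, mM, non-negative.
#' @return An object of class `aif_curve`.
#' @export
aif_curve <- function(times, cp) {
  stopifnot(length(times) == length(cp), all(diff(times) > 0),
            all(is.finite(cp)), all(cp >= -1e-12))
  structure(list(times = as.numeric(times), cp = pmax(as.numeric(cp), 0)),
            class = "aif_curve")
}

#' @export
print.aif_curve <- function(x, ...) {
  cat(sprintf("AIF: %d samples over %.1f s, peak %.2f mM\n",
              length(x$times), max(x$times), max(x$cp)))
  invisible(x)
}
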