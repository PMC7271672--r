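#' DCE acquisition protocol
#'
#' Describes the dynamic spoiled-gradient-echo (SPGR) acquisition that the
#' signal model and the synthetic phantoms share: repetition time, flip
#' angle, the number of pre-injection (baseline) and total dynamic phases,
#' and the temporal resolution. Contrast-agent relaxivity and the assumed
#' native tissue relaxation time T10 travel with the protocol because the
#' signal-to-concentration conversion needs them.
#'
#' Defaults correspond to a brain DCE protocol: TR 4.5 ms, flip angle 25
#' degrees, 10 baseline + 30 dynamic phases at 5.5 s temporal resolution,
#' gadopentetate r1 relaxivity 4.5 /(s mM). T10 is a single assumed value
#' per field strength (0.8 or 1 s are the common choices when no T1 map is
#' acquired); which value maps to which field strength is site policy, so
#' it is plain configuration here.
#'
#' @param repetition_time repetition time TR, seconds.
#' @param flip_angle flip angle, degrees, in (0, 90].
#' @param n_baseline_phases number of pre-injection phases.
#' @param n_total_phases total number of dynamic phases.
#' @param temporal_resolution time between phases, seconds.
#' @param field_strength_label `"1.5T"` or `"3T"` (label only).
#' @param relaxivity_r1 contrast agent longitudinal relaxivity, 1/(s mM).
#' @param T10_default assumed native T1, seconds.
#' @return An object of class `dce_protocol`.
#' @examples
#' p <- acquisition_protocol()
#' protocol_times(p)[1:5]
#' @export
acquisition_protocol <- function(repetition_time = 0.0045,
                                 flip_angle = 25,
                                 n_baseline_phases = 10,
                                 n_total_phases = 40,
                                 temporal_resolution = 5.5,
                                 field_strength_label = c("1.5T", "3T"),
                                 relaxivity_r1 = 4.5,
                                 T10_default = 1.0) {
  field_strength_label <- match.arg(field_strength_label)
  stopifnot(repetition_time > 0, temporal_resolution > 0,
            flip_angle > 0, flip_angle <= 90,
            n_baseline_phases >= 1,
            n_baseline_phases < n_total_phases,
            relaxivity_r1 > 0, T10_default > 0)
  structure(list(repetition_time = repetition_time,
                 flip_angle = flip_angle,
                 n_baseline_phases = as.integer(n_baseline_phases),
                 n_total_phases = as.integer(n_total_phases),
                 temporal_resolution = temporal_resolution,
                 field_strength_label = field_strength_label,
                 relaxivity_r1 = relaxivity_r1,
                 T10_default = T10_default),
            class = "dce_protocol")
}

#' Acquisition time grid
#'
#' Mid-acquisition times of the dynamic phases, starting at 0.
#'
#' @param protocol a [acquisition_protocol()] object.
#' @return Numeric vector of length `n_total_phases`, seconds.
#' @export
protocol_times <- function(protocol) {
  stopifnot(inherits(protocol, "dce_protocol"))
  (seq_len(protocol$n_total_phases) - 1) * protocol$temporal_resolution
}

#' @export
print.dce_protocol <- function(x, ...) {
  cat(sprintf("DCE protocol (%s): TR %.2f ms, FA %g deg, %d+%d phases @ %.2f s\n",
              x$field_strength_label, x$repetition_time * 1e3, x$flip_angle,
              x$n_baseline_phases,
              x$n_total_phases - x$n_baseline_phases,
              x$temporal_resolution))
  invisible(x)
}
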