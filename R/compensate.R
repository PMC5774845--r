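# Energy-spectral-density compensation: before interpolation, each
# microphone's received ESD is corrected back to a reference range by
# removing spherical spreading, atmospheric absorption, microphone
# sensitivity and microphone directivity.

#' Microphone specification
#'
#' @param id Microphone identifier.
#' @param position Length-3 position, metres, room frame.
#' @param facing Unit vector the microphone points along.
#' @param sensitivity A function `f(frequency_hz) -> dB` added to the
#'   acoustic level by the microphone (flat 0 dB by default), defined over
#'   10-100 kHz.
#' @param directivity A function `f(angle_deg, frequency_hz) -> dB` of
#'   off-axis response (flat 0 dB by default).
#' @return A `mic_spec` object.
#' @export
mic_spec <- function(id, position, facing = c(0, 0, 0) - position,
                     sensitivity = function(f) rep(0, length(f)),
                     directivity = function(angle, f) 0) {
  facing <- facing / sqrt(sum(facing^2))
  structure(
    list(id = id, position = position, facing = facing,
         sensitivity = sensitivity, directivity = directivity),
    class = "mic_spec"
  )
}

#' Compensate a received ESD for propagation and microphone response
#'
#' Adds back spherical spreading `20 log10(range / r_ref)` and atmospheric
#' absorption `alpha(f) * range` (ISO 9613-1), subtracts the microphone
#' sensitivity and the microphone directivity at the arrival angle. The
#' result is the source-referenced ESD at the reference range, so applying
#' the same losses and compensating is an exact round trip.
#'
#' @param esd Data frame with columns `frequency` (Hz) and `esd` (dB).
#' @param mic A [mic_spec()].
#' @param range Source-to-microphone range, metres; must exceed `r_ref`.
#' @param medium An [acoustic_medium()].
#' @param r_ref Reference range, metres.
#' @param arrival_angle Off-axis arrival angle at the microphone, degrees
#'   (for the directivity correction).
#' @param absorption Logical; apply the atmospheric absorption term.
#' @return `esd` with the `esd` column compensated.
#' @export
compensate_esd <- function(esd, mic, range, medium = acoustic_medium(),
                           r_ref = 0.1, arrival_angle = 0, absorption = TRUE) {
  stopifnot(all(c("frequency", "esd") %in% names(esd)))
  if (range < r_ref) stop("range must exceed the reference range r_ref")
  f <- esd$frequency
  if (any(f < 10e3 - 1e-6) || any(f > 100e3 + 1e-6)) {
    stop("frequency outside the 10-100 kHz sensitivity band")
  }
  comp <- esd$esd + 20 * log10(range / r_ref)
  if (absorption) comp <- comp + atmospheric_absorption(f, medium) * range
  comp <- comp - mic$sensitivity(f) - mic$directivity(arrival_angle, f)
  dplyr::mutate(esd, esd = comp)
}

# forward model of the same losses; synthesize_esd uses this so that
# compensate_esd inverts it exactly
apply_propagation <- function(esd_db, frequency, mic, range,
                              medium = acoustic_medium(), r_ref = 0.1,
                              arrival_angle = 0, absorption = TRUE) {
  out <- esd_db - 20 * log10(range / r_ref)
  if (absorption) out <- out - atmospheric_absorption(frequency, medium) * range
  out + mic$sensitivity(frequency) + mic$directivity(arrival_angle, frequency)
}
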