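#' Acoustic propagation medium
#'
#' Describes the air in the flight room: sound speed, temperature, relative
#' humidity and static pressure. The sound speed may be supplied directly or
#' derived from temperature (`c = 331.3 * sqrt(1 + T/273.15)` m/s); if both
#' are given they must agree within 1 m/s.
#'
#' @param sound_speed Sound speed in m/s, or `NULL` to derive from
#'   temperature.
#' @param temperature Air temperature, degrees Celsius.
#' @param humidity Relative humidity, percent.
#' @param pressure Static pressure, kPa.
#' @return An object of class `acoustic_medium`.
#' @examples
#' acoustic_medium()              # 20 C, 50% RH, c = 343 m/s
#' acoustic_medium(temperature = 25)
#' @export
acoustic_medium <- function(sound_speed = 343, temperature = 20,
                            humidity = 50, pressure = 101.325) {
  c_derived <- 331.3 * sqrt(1 + temperature / 273.15)
  if (is.null(sound_speed)) {
    sound_speed <- c_derived
  } else if (abs(sound_speed - c_derived) > 1) {
    stop(sprintf(
      "sound_speed %.1f m/s inconsistent with temperature %.1f C (derived %.1f m/s)",
      sound_speed, temperature, c_derived
    ))
  }
  stopifnot(sound_speed > 0, humidity >= 0, humidity <= 100, pressure > 0)
  structure(
    list(
      sound_speed = sound_speed, temperature = temperature,
      humidity = humidity, pressure = pressure
    ),
    class = "acoustic_medium"
  )
}

#' @export
print.acoustic_medium <- function(x, ...) {
  cat(sprintf(
    "<acoustic_medium> c = %.1f m/s, %.1f C, %.0f%% RH, %.2f kPa\n",
    x$sound_speed, x$temperature, x$humidity, x$pressure
  ))
  invisible(x)
}

#' Acoustic wavenumber
#'
#' `k = omega / c = 2 pi f / c`, in rad/m.
#'
#' @param frequency Frequency in Hz.
#' @param medium An [acoustic_medium()].
#' @return Wavenumber(s) in rad/m.
#' @export
wavenumber <- function(frequency, medium = acoustic_medium()) {
  stopifnot(all(frequency > 0))
  2 * pi * frequency / medium$sound_speed
}

#' Atmospheric absorption coefficient (ISO 9613-1)
#'
#' Pure-tone atmospheric attenuation in dB/m from the analytic ISO 9613-1
#' model: classical (translational/rotational) absorption plus vibrational
#' relaxation of oxygen and nitrogen, as functions of temperature, humidity
#' and static pressure.
#'
#' @inheritParams wavenumber
#' @return Attenuation in dB per metre, same length as `frequency`.
#' @examples
#' atmospheric_absorption(35e3)  # ~ 1 dB/m at room conditions
#' @export
atmospheric_absorption <- function(frequency, medium = acoustic_medium()) {
  f <- frequency
  T_k <- medium$temperature + 273.15
  T0 <- 293.15
  T01 <- 273.16
  pa <- medium$pressure
  pr <- 101.325
  # molar concentration of water vapour (%), from RH via saturation pressure
  psat_ratio <- 10^(-6.8346 * (T01 / T_k)^1.261 + 4.6151)
  h <- medium$humidity * psat_ratio / (pa / pr)
  frO <- (pa / pr) * (24 + 4.04e4 * h * (0.02 + h) / (0.391 + h))
  frN <- (pa / pr) * (T_k / T0)^(-1 / 2) *
    (9 + 280 * h * exp(-4.170 * ((T_k / T0)^(-1 / 3) - 1)))
  8.686 * f^2 * (
    1.84e-11 * (pa / pr)^(-1) * (T_k / T0)^(1 / 2) +
      (T_k / T0)^(-5 / 2) * (
        0.01275 * exp(-2239.1 / T_k) / (frO + f^2 / frO) +
          0.1068 * exp(-3352 / T_k) / (frN + f^2 / frN)
      )
  )
}
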