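# Spatial-sampling quality criteria for individual clicks. A click is kept
# only if the microphone array sampled its beam well enough: wide
# azimuth/elevation coverage, the loudest microphone not on the edge of the
# sampled region, enough neighbours around the loudest microphone, and
# adequate level above the noise floor. Thresholds are configurable; the
# defaults are declared approximations.

#' Default click quality criteria
#'
#' @param az_span_min Minimum azimuthal span of microphone directions, deg.
#' @param el_span_min Minimum elevational span, deg.
#' @param n_near_min Minimum number of microphones within
#'   `near_radius` of the loudest microphone.
#' @param near_radius Great-circle radius defining "near", deg.
#' @param snr_min Minimum peak received level above the noise floor, dB.
#' @param noise_floor_db Noise floor reference level, dB.
#' @return A named list of thresholds.
#' @export
quality_criteria <- function(az_span_min = 120, el_span_min = 60,
                             n_near_min = 5, near_radius = 30,
                             snr_min = 10, noise_floor_db = 30) {
  list(
    az_span_min = az_span_min, el_span_min = el_span_min,
    n_near_min = n_near_min, near_radius = near_radius,
    snr_min = snr_min, noise_floor_db = noise_floor_db
  )
}

#' Evaluate the five spatial-sampling quality criteria for a click
#'
#' Criteria: (1) azimuthal span of the projected microphone directions at
#' least `az_span_min`; (2) elevational span at least `el_span_min`;
#' (3) the loudest microphone is not on the convex hull boundary of the
#' sampled directions (under the Eckert IV projection); (4) at least
#' `n_near_min` microphones lie within `near_radius` degrees (great
#' circle) of the loudest microphone; (5) the peak received level is at
#' least `snr_min` dB above the noise floor.
#'
#' @param samples Data frame with per-microphone columns `azimuth`,
#'   `elevation` (degrees, bat frame) and `db` (received level at the
#'   reference frequency).
#' @param criteria A [quality_criteria()] list.
#' @return A list with `pass` (logical) and `report`, a tibble with one row
#'   per criterion.
#' @export
quality_filter <- function(samples, criteria = quality_criteria()) {
  needed <- c("az_span_min", "el_span_min", "n_near_min", "near_radius",
              "snr_min", "noise_floor_db")
  if (!all(needed %in% names(criteria))) {
    stop("criteria configuration is missing: ",
         paste(setdiff(needed, names(criteria)), collapse = ", "))
  }
  stopifnot(all(c("azimuth", "elevation", "db") %in% names(samples)))

  az_span <- diff(range(samples$azimuth))
  el_span <- diff(range(samples$elevation))
  imax <- which.max(samples$db)

  proj <- eckert4(samples$azimuth, samples$elevation)
  hull <- grDevices::chull(proj$x, proj$y)
  on_hull <- imax %in% hull

  u <- sph_to_unit(samples$azimuth, samples$elevation)
  gc <- rad2deg(drop(great_circle(u, u[imax, , drop = FALSE])))
  n_near <- sum(gc <= criteria$near_radius) - 1  # exclude the max mic itself

  snr <- max(samples$db) - criteria$noise_floor_db

  report <- tibble::tibble(
    criterion = c("azimuth_span", "elevation_span", "max_mic_interior",
                  "neighbours_near_max", "snr"),
    value = c(az_span, el_span, as.numeric(!on_hull), n_near, snr),
    threshold = c(criteria$az_span_min, criteria$el_span_min, 1,
                  criteria$n_near_min, criteria$snr_min),
    pass = c(
      az_span >= criteria$az_span_min,
      el_span >= criteria$el_span_min,
      !on_hull,
      n_near >= criteria$n_near_min,
      snr >= criteria$snr_min
    )
  )
  list(pass = all(report$pass), report = report)
}
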