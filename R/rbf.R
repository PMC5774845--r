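# Radial basis function interpolation of scattered directional samples.
# The kernel is a thin-plate spline in the great-circle angle between
# directions, so the interpolant respects the spherical geometry of the
# measurement domain and incorporates every microphone sample exactly
# (no smoothing).

tps_kernel <- function(r) {
  out <- r * 0
  pos <- r > 1e-14
  out[pos] <- r[pos]^2 * log(r[pos])
  out
}

#' Interpolate scattered beam samples onto a direction grid
#'
#' Exact thin-plate-spline interpolation (with a constant offset term) of
#' per-microphone beam energy samples, using great-circle angles as the
#' radial distance. The gridded result is renormalized so its maximum is
#' 0 dB.
#'
#' @param samples Data frame with columns `azimuth`, `elevation` (degrees)
#'   and `db`. At least 5 samples spanning more than 90 degrees of azimuth;
#'   duplicate directions are an error.
#' @param grid A [direction_grid()].
#' @param frequency Optional frequency label (Hz) carried in the result.
#' @param support_radius Grid directions farther than this (degrees, great
#'   circle) from every sample are outside the measured support and are
#'   set to the bottom of the sample dynamic range rather than
#'   extrapolated.
#' @return A `reconstructed_beam` (also a `beam_pattern`): normalized dB on
#'   the grid, the sample table, the interpolation weights and the
#'   normalization offset that was subtracted.
#' @export
rbf_interpolate <- function(samples, grid = direction_grid(),
                            frequency = NA_real_, support_radius = 25) {
  stopifnot(all(c("azimuth", "elevation", "db") %in% names(samples)))
  if (nrow(samples) < 5) stop("need at least 5 samples for interpolation")
  if (diff(range(samples$azimuth)) <= 90) {
    stop("samples must span more than 90 degrees of azimuth")
  }
  su <- sph_to_unit(samples$azimuth, samples$elevation)
  gc <- great_circle(su, su)
  dup <- gc < 1e-6  # ~ 6e-5 degrees; acos() noise floor for unit vectors
  diag(dup) <- FALSE
  if (any(dup)) stop("duplicate sample directions")
  K <- tps_kernel(gc)

  n <- nrow(su)
  A <- rbind(cbind(K, 1), c(rep(1, n), 0))
  sol <- solve(A, c(samples$db, 0))
  w <- sol[1:n]
  const <- sol[n + 1]

  # Outside the sampled support the thin-plate interpolant is pure
  # extrapolation and can diverge inside coverage holes. The field is
  # clamped to the beam's peak level - the interpolant's maximum near the
  # loudest sample (the peak usually falls between microphones, so the
  # loudest sample alone would underestimate it) - and floored below the
  # sample dynamic range; grid directions with no sample within
  # `support_radius` are floored outright.
  gdist <- great_circle(grid$units, su)
  vals <- drop(tps_kernel(gdist) %*% w) + const
  imax <- which.max(samples$db)
  near_peak <- drop(great_circle(grid$units, su[imax, , drop = FALSE])) <=
    deg2rad(15)
  peak_est <- max(samples$db[imax], vals[near_peak])
  clamp <- c(min(samples$db) - 10, peak_est)
  vals <- pmin(pmax(vals, clamp[1]), clamp[2])
  vals[apply(gdist, 1, min) > deg2rad(support_radius)] <- clamp[1]
  offset <- max(vals)
  rb <- new_beam_pattern(matrix(vals, ncol = 1), grid, frequency,
                         metadata = list(model = "reconstruction"))
  rb$samples <- tibble::as_tibble(samples)
  rb$weights <- w
  rb$const <- const
  rb$offset <- offset
  rb$clamp <- clamp
  class(rb) <- c("reconstructed_beam", class(rb))
  rb
}

#' Evaluate a reconstructed beam's interpolant at arbitrary directions
#'
#' Evaluates the underlying radial basis function exactly (not via the
#' grid), on the same normalized scale as the gridded pattern.
#'
#' @param beam A [rbf_interpolate()] result.
#' @param azimuth,elevation Directions, degrees.
#' @return Normalized dB values.
#' @export
rbf_predict <- function(beam, azimuth, elevation) {
  su <- sph_to_unit(beam$samples$azimuth, beam$samples$elevation)
  u <- sph_to_unit(azimuth, elevation)
  v <- drop(tps_kernel(great_circle(u, su)) %*% beam$weights) + beam$const
  pmin(pmax(v, beam$clamp[1]), beam$clamp[2]) - beam$offset
}
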