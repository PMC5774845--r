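# Eckert IV equal-area pseudocylindrical projection. Beam contours are
# extracted and ellipse-fitted under this projection (its elevation
# "stretch" is compensated when angular extents are reported). The radius
# is chosen as 180/pi so projected coordinates are commensurate with
# degrees near the origin.

ECKERT_R <- 180 / pi
ECKERT_CX <- 2 / sqrt(4 * pi + pi^2)
ECKERT_CY <- 2 * sqrt(pi / (4 + pi))

eckert_theta <- function(lat_rad, tol = 1e-10, max_iter = 100) {
  rhs <- (2 + pi / 2) * sin(lat_rad)
  theta <- lat_rad / 2
  for (i in seq_len(max_iter)) {
    g <- theta + sin(theta) * cos(theta) + 2 * sin(theta) - rhs
    gp <- 1 + cos(2 * theta) + 2 * cos(theta)
    step <- g / pmax(gp, 1e-6)
    theta <- theta - pmin(pmax(step, -0.5), 0.5)
    if (max(abs(g)) < tol) break
  }
  pmin(pmax(theta, -pi / 2), pi / 2)
}

#' Eckert IV forward projection
#'
#' Maps azimuth/elevation (degrees) to equal-area projected coordinates.
#' The auxiliary angle is solved by damped Newton iteration to 1e-10.
#'
#' @param azimuth,elevation Degrees; azimuth in \[-180, 180\], elevation in
#'   \[-90, 90\].
#' @return A tibble with projected columns `x`, `y`.
#' @examples
#' eckert4(0, 0)  # origin maps to the origin
#' @export
eckert4 <- function(azimuth, elevation) {
  stopifnot(all(abs(azimuth) <= 180 + 1e-9), all(abs(elevation) <= 90 + 1e-9))
  lam <- deg2rad(azimuth)
  theta <- eckert_theta(deg2rad(elevation))
  tibble::tibble(
    x = ECKERT_CX * ECKERT_R * lam * (1 + cos(theta)),
    y = ECKERT_CY * ECKERT_R * sin(theta)
  )
}

#' Eckert IV inverse projection
#'
#' @param x,y Projected coordinates from [eckert4()].
#' @return A tibble with columns `azimuth`, `elevation` in degrees.
#' @export
eckert4_inverse <- function(x, y) {
  theta <- asin(pmin(1, pmax(-1, y / (ECKERT_CY * ECKERT_R))))
  lat <- asin(pmin(1, pmax(-1,
    (theta + sin(theta) * cos(theta) + 2 * sin(theta)) / (2 + pi / 2)
  )))
  lam <- x / (ECKERT_CX * ECKERT_R * (1 + cos(theta)))
  tibble::tibble(azimuth = rad2deg(lam), elevation = rad2deg(lat))
}

# local projection scale factors (projected units per degree of azimuth /
# elevation) at a point; used to convert projected ellipse extents into
# angular widths
eckert4_scales <- function(azimuth, elevation, delta = 1e-4) {
  fx <- eckert4(azimuth + delta, elevation)$x - eckert4(azimuth - delta, elevation)$x
  fy <- eckert4(azimuth, elevation + delta)$y - eckert4(azimuth, elevation - delta)$y
  c(sx = fx / (2 * delta), sy = fy / (2 * delta))
}
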