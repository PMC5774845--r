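# Internal geometry helpers. Angles cross the API in degrees; internals use
# radians. Bat frame convention: x = head aim (rostral), z = head normal
# (dorsal), y = z cross x (bat's left). Azimuth positive to the bat's left,
# elevation positive dorsal.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Direction cosines from azimuth and elevation
#'
#' Converts azimuth/elevation (degrees, bat-frame convention: azimuth
#' positive to the left, elevation positive dorsal) into unit vectors.
#'
#' @param azimuth,elevation Numeric vectors, degrees.
#' @return A numeric matrix with one row per direction and columns x, y, z.
#' @export
sph_to_unit <- function(azimuth, elevation) {
  az <- deg2rad(azimuth)
  el <- deg2rad(elevation)
  cbind(x = cos(el) * cos(az), y = cos(el) * sin(az), z = sin(el))
}

#' Azimuth and elevation from direction vectors
#'
#' Inverse of [sph_to_unit()]. Vectors need not be normalized.
#'
#' @param v Numeric matrix (n x 3) or length-3 vector.
#' @return A tibble with columns `azimuth`, `elevation` (degrees).
#' @export
unit_to_sph <- function(v) {
  if (is.null(dim(v))) v <- matrix(v, ncol = 3)
  n <- sqrt(rowSums(v^2))
  if (any(n == 0)) stop("zero-length direction vector")
  tibble::tibble(
    azimuth = rad2deg(atan2(v[, 2], v[, 1])),
    elevation = rad2deg(asin(pmin(1, pmax(-1, v[, 3] / n))))
  )
}

normalize_rows <- function(m) {
  if (is.null(dim(m))) m <- matrix(m, ncol = 3)
  m / sqrt(rowSums(m^2))
}

cross3 <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

# Great-circle angle (radians) between unit-vector rows of a and b:
# returns |a| x |b| matrix.
great_circle <- function(a, b) {
  ct <- tcrossprod(a, b)
  acos(pmin(pmax(ct, -1), 1))  # argument order preserves the dim attribute
}

# Rotation matrix about an arbitrary unit axis by angle (radians),
# Rodrigues form.
rotation_about <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# normalize shifted spherical coordinates: wrap elevations beyond +/-90
# over the pole (flipping azimuth by 180) and azimuths into (-180, 180]
wrap_az_el <- function(azimuth, elevation) {
  over <- elevation > 90
  under <- elevation < -90
  elevation[over] <- 180 - elevation[over]
  elevation[under] <- -180 - elevation[under]
  azimuth[over | under] <- azimuth[over | under] + 180
  azimuth <- ((azimuth + 180) %% 360) - 180
  azimuth[azimuth == -180] <- 180
  list(azimuth = azimuth, elevation = elevation)
}
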