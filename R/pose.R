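# Bat head pose: position plus an orthonormal head frame (aim = rostral x,
# normal = dorsal z, left = z cross x). Poses come either from the three
# head-stage markers (front marker a, rear markers b and c) or, when
# markers drop out, from the horizontal tangent of the flight trajectory
# with the floor-plane normal standing in for the head normal.

new_bat_pose <- function(position, aim, normal, source = "markers") {
  aim <- aim / sqrt(sum(aim^2))
  # re-orthogonalize the normal against the aim
  normal <- normal - sum(normal * aim) * aim
  nn <- sqrt(sum(normal^2))
  if (nn < 1e-12) stop("head normal parallel to head aim")
  normal <- normal / nn
  structure(
    list(position = position, aim = aim, normal = normal,
         left = cross3(normal, aim), source = source),
    class = "bat_pose"
  )
}

#' @export
print.bat_pose <- function(x, ...) {
  cat(sprintf(
    "<bat_pose> at (%.2f, %.2f, %.2f), aim (%.2f, %.2f, %.2f) [%s]\n",
    x$position[1], x$position[2], x$position[3],
    x$aim[1], x$aim[2], x$aim[3], x$source
  ))
  invisible(x)
}

#' Head pose from the three head-stage markers
#'
#' The head aim points from the midpoint of the rear markers `b` and `c`
#' toward the front marker `a`; the head normal is the cross product
#' `(a - b) x (a - c)`, sign-flipped if needed so it points dorsally
#' (`up` hemisphere). Marker coordinates and the pose position are in the
#' room frame (metres).
#'
#' @param a,b,c Length-3 marker positions: front, rear-left, rear-right.
#' @param up Reference up direction used to fix the normal's sign.
#' @return A `bat_pose` located at the midpoint of `b` and `c`.
#' @examples
#' head_pose_from_markers(c(1, 0, 0), c(-1, 1, 0), c(-1, -1, 0))
#' @export
head_pose_from_markers <- function(a, b, c, up = c(0, 0, 1)) {
  mid <- (b + c) / 2
  aim <- a - mid
  if (sqrt(sum(aim^2)) < 1e-12) stop("markers are degenerate (a at rear midpoint)")
  normal <- cross3(a - b, a - c)
  nn <- sqrt(sum(normal^2))
  if (nn < 1e-12) stop("markers are collinear")
  normal <- normal / nn
  if (sum(normal * up) < 0) normal <- -normal
  new_bat_pose(mid, aim, normal, source = "markers")
}

#' Head pose from the flight trajectory (marker-dropout fallback)
#'
#' When one or more markers are missing, the head aim is approximated by
#' the tangent of the smoothed trajectory projected onto the horizontal
#' (x-y) plane, and the head normal by the floor-plane normal (0, 0, 1).
#'
#' @param trajectory Data frame with columns `time`, `x`, `y`, `z` (room
#'   frame, metres); at least 3 samples bracketing `t`.
#' @param t Time at which the pose is needed.
#' @return A `bat_pose` with `source = "trajectory"`.
#' @export
head_pose_fallback <- function(trajectory, t) {
  stopifnot(all(c("time", "x", "y", "z") %in% names(trajectory)))
  if (nrow(trajectory) < 3) stop("need at least 3 trajectory samples")
  if (t < min(trajectory$time) || t > max(trajectory$time)) {
    stop("time t not bracketed by the trajectory")
  }
  fx <- stats::splinefun(trajectory$time, trajectory$x, method = "natural")
  fy <- stats::splinefun(trajectory$time, trajectory$y, method = "natural")
  fz <- stats::splinefun(trajectory$time, trajectory$z, method = "natural")
  vel <- c(fx(t, deriv = 1), fy(t, deriv = 1), fz(t, deriv = 1))
  horiz <- c(vel[1], vel[2], 0)
  if (sqrt(sum(horiz^2)) < 1e-9) {
    stop("trajectory is stationary (or purely vertical) at t; no fallback aim")
  }
  new_bat_pose(
    position = c(fx(t), fy(t), fz(t)),
    aim = horiz, normal = c(0, 0, 1), source = "trajectory"
  )
}

#' Project microphones into the bat-centred azimuth-elevation frame
#'
#' Transforms microphone positions from the room frame into spherical
#' coordinates around the bat's head: azimuth positive to the bat's left,
#' elevation positive dorsal.
#'
#' @param mics Data frame with microphone positions in columns `x`, `y`,
#'   `z` (metres, room frame).
#' @param pose A `bat_pose`.
#' @return `mics` with added columns `azimuth`, `elevation` (degrees) and
#'   `range` (metres).
#' @export
project_mics_to_bat_frame <- function(mics, pose) {
  d <- as.matrix(mics[, c("x", "y", "z")]) -
    matrix(pose$position, nrow(mics), 3, byrow = TRUE)
  rng <- sqrt(rowSums(d^2))
  if (any(rng < 1e-9)) stop("microphone coincides with the bat position")
  local <- d %*% cbind(pose$aim, pose$left, pose$normal)
  ae <- unit_to_sph(local)
  dplyr::mutate(mics, azimuth = ae$azimuth, elevation = ae$elevation,
                range = rng)
}

# rotate a pose's frame about its normal (dorsal) axis by angle degrees
# (positive toward the bat's left); used for click aim offsets
rotate_pose_azimuth <- function(pose, angle_deg) {
  R <- rotation_about(pose$normal, deg2rad(angle_deg))
  new_bat_pose(pose$position, drop(R %*% pose$aim), pose$normal, pose$source)
}
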