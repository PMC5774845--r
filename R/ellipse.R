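# Main-lobe geometry: the -3 dB iso-contour of a normalized beam pattern is
# extracted under the Eckert IV projection and summarized by a direct
# least-squares ellipse fit. The beam center at a frequency is defined as
# the center of that best-fitting ellipse.

#' Extract the -3 dB contour of a beam pattern
#'
#' Finds the iso-contour at `level` dB on the grid and returns the closed
#' contour enclosing the global maximum, projected with [eckert4()]. A
#' contour that touches the grid boundary is flagged via the `boundary`
#' attribute (it feeds the sampling-quality criteria).
#'
#' @param beam A `beam_pattern` (max 0 dB).
#' @param frequency Which frequency slice to contour.
#' @param level Contour level in dB (default -3).
#' @return A tibble of contour vertices with columns `azimuth`,
#'   `elevation`, `x`, `y`; attribute `boundary` is `TRUE` if the selected
#'   contour was clipped by the grid edge.
#' @export
contour_minus3db <- function(beam, frequency = beam$frequency[1], level = -3) {
  m <- beam_slice(beam, frequency)
  gaz <- beam$grid$azimuth
  gel <- beam$grid$elevation
  if (max(m) < level) stop("beam has no region above the contour level")
  if (min(m) > level) {
    stop("beam is entirely above ", level, " dB on the grid; no closed contour")
  }
  cl <- grDevices::contourLines(gaz, gel, m, levels = level)
  if (length(cl) == 0) stop("no contour found at ", level, " dB")

  if (!is.null(beam$anchors) &&
      any(abs(beam$anchors$frequency - frequency) < 1e-6)) {
    # measured beams: anchor the main lobe at the loudest measurement, not
    # at the grid maximum (the interpolant can overshoot between samples)
    a <- beam$anchors[which(abs(beam$anchors$frequency - frequency) < 1e-6)[1], ]
    peak <- c(a$azimuth, a$elevation)
  } else if (!is.null(beam$samples)) {
    imax <- which.max(beam$samples$db)
    peak <- c(beam$samples$azimuth[imax], beam$samples$elevation[imax])
  } else {
    imax <- arrayInd(which.max(m), dim(m))
    peak <- c(gaz[imax[1]], gel[imax[2]])
  }

  on_boundary <- function(cc) {
    eps <- 1e-9
    any(abs(cc$x - min(gaz)) < eps | abs(cc$x - max(gaz)) < eps |
          abs(cc$y - min(gel)) < eps | abs(cc$y - max(gel)) < eps)
  }
  closed <- !vapply(cl, on_boundary, logical(1))
  encl <- vapply(cl, function(cc) point_in_polygon(peak, cc$x, cc$y), logical(1))

  pick <- which(closed & encl)
  boundary_flag <- FALSE
  if (length(pick) == 0) {
    pick <- which(encl)
    boundary_flag <- TRUE
  }
  if (length(pick) == 0) {
    # fall back to the contour whose vertices are closest to the peak
    d2 <- vapply(cl, function(cc) min((cc$x - peak[1])^2 + (cc$y - peak[2])^2),
                 numeric(1))
    pick <- which.min(d2)
    boundary_flag <- !closed[pick]
  }
  cc <- cl[[pick[1]]]
  proj <- eckert4(cc$x, cc$y)
  out <- tibble::tibble(azimuth = cc$x, elevation = cc$y,
                        x = proj$x, y = proj$y)
  attr(out, "boundary") <- boundary_flag
  attr(out, "level") <- level
  out
}

# even-odd ray crossing test
point_in_polygon <- function(p, vx, vy) {
  n <- length(vx)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if ((vy[i] > p[2]) != (vy[j] > p[2]) &&
        p[1] < (vx[j] - vx[i]) * (p[2] - vy[i]) / (vy[j] - vy[i]) + vx[i]) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

#' Direct least-squares ellipse fit
#'
#' Fits a conic constrained to be an ellipse (numerically stable direct
#' least-squares formulation) to projected contour points, and reports the
#' center mapped back to azimuth/elevation through the inverse projection,
#' with angular extents compensated for the projection's local scale.
#'
#' @param points Data frame with projected columns `x`, `y` (at least 5
#'   non-degenerate points), as produced by [contour_minus3db()].
#' @return An `ellipse_fit`: projected center and semi-axes, rotation
#'   (degrees), `center` (azimuth, elevation, degrees), `az_extent` and
#'   `el_extent` (degrees) and `aspect_ratio` (elevation / azimuth extent).
#' @export
fit_ellipse <- function(points) {
  x <- points$x
  y <- points$y
  if (length(x) < 5) stop("need at least 5 points to fit an ellipse")
  mx <- mean(x); my <- mean(y)
  sc <- max(stats::sd(x), stats::sd(y))
  if (sc < 1e-12) stop("degenerate points; cannot fit an ellipse")
  xs <- (x - mx) / sc
  ys <- (y - my) / sc

  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)), error = function(e) {
    stop("degenerate points; best-fitting conic is not an ellipse")
  })
  M <- S1 + S2 %*% Tm
  Minv_c <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(Minv_c)
  vecs <- Re(ev$vectors)
  cond <- 4 * vecs[1, ] * vecs[3, ] - vecs[2, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0) stop("best-fitting conic is not an ellipse")
  a1 <- vecs[, ok[1]]
  coefs <- c(a1, Tm %*% a1)  # A x^2 + B xy + C y^2 + D x + E y + F (scaled)

  # un-scale back to original coordinates
  A <- coefs[1] / sc^2
  B <- coefs[2] / sc^2
  C <- coefs[3] / sc^2
  D <- coefs[4] / sc - 2 * A * mx - B * my
  E <- coefs[5] / sc - 2 * C * my - B * mx
  Fc <- coefs[6] + A * mx^2 + B * mx * my + C * my^2 -
    coefs[4] * mx / sc - coefs[5] * my / sc

  # normalize sign so the quadratic form is positive definite
  if (A < 0) {
    A <- -A; B <- -B; C <- -C; D <- -D; E <- -E; Fc <- -Fc
  }
  den <- B^2 - 4 * A * C
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  V <- A * cx^2 + B * cx * cy + C * cy^2 + D * cx + E * cy + Fc
  M2 <- matrix(c(A, B / 2, B / 2, C), 2)
  ee <- eigen(M2, symmetric = TRUE)  # eigenvalues decreasing
  if (V >= 0 || any(ee$values <= 0)) stop("best-fitting conic is not an ellipse")
  a_semi <- sqrt(-V / ee$values[2])  # major axis: smallest eigenvalue
  b_semi <- sqrt(-V / ee$values[1])
  scale_ref <- max(abs(c(A, B, C)))
  if (abs(B) < 1e-9 * scale_ref && abs(A - C) < 1e-9 * scale_ref) {
    rot <- 0  # circle: rotation reported as 0 by convention
  } else {
    v_major <- ee$vectors[, 2]
    rot <- rad2deg(atan2(v_major[2], v_major[1]))
    rot <- ((rot + 90) %% 180) - 90
  }

  ctr_ae <- eckert4_inverse(cx, cy)
  scl <- eckert4_scales(ctr_ae$azimuth, ctr_ae$elevation)
  phi <- deg2rad(rot)
  x_extent <- 2 * sqrt((a_semi * cos(phi))^2 + (b_semi * sin(phi))^2)
  y_extent <- 2 * sqrt((a_semi * sin(phi))^2 + (b_semi * cos(phi))^2)
  az_extent <- x_extent / scl["sx"]
  el_extent <- y_extent / scl["sy"]

  structure(
    list(
      center_xy = c(x = cx, y = cy),
      semi_axes = c(major = a_semi, minor = b_semi),
      rotation = rot,
      center = c(azimuth = ctr_ae$azimuth, elevation = ctr_ae$elevation),
      az_extent = unname(az_extent),
      el_extent = unname(el_extent),
      aspect_ratio = unname(el_extent / az_extent),
      conic = c(A = A, B = B, C = C, D = D, E = E, F = Fc)
    ),
    class = "ellipse_fit"
  )
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf(
    "<ellipse_fit> center (%.2f, %.2f) deg, extents %.1f x %.1f deg, aspect %.2f\n",
    x$center[1], x$center[2], x$az_extent, x$el_extent, x$aspect_ratio
  ))
  invisible(x)
}

#' @method tidy ellipse_fit
#' @export
tidy.ellipse_fit <- function(x, ...) {
  tibble::tibble(
    term = c("center_azimuth", "center_elevation", "az_extent", "el_extent",
             "aspect_ratio", "rotation"),
    estimate = c(x$center[1], x$center[2], x$az_extent, x$el_extent,
                 x$aspect_ratio, x$rotation)
  )
}

#' Beam center of a beam pattern at one frequency
#'
#' The center of the best-fitting ellipse to the -3 dB contour at the
#' requested frequency: the operational definition of where the sonar beam
#' points.
#'
#' @param beam A `beam_pattern`.
#' @param frequency Frequency slice, Hz.
#' @param level Contour level, dB.
#' @return Named numeric `c(azimuth, elevation)` in degrees.
#' @export
beam_center <- function(beam, frequency = beam$frequency[1], level = -3) {
  fit <- fit_ellipse(contour_minus3db(beam, frequency, level))
  c(azimuth = unname(fit$center[1]), elevation = unname(fit$center[2]))
}

#' Energy-weighted mean direction of the near-peak region
#'
#' The mean direction of all grid points within `threshold` dB of the peak
#' (by default > -1 dB). Used to verify that the ellipse-center definition
#' of the beam center agrees with the bulk of the high-energy region.
#'
#' @param beam A `beam_pattern`.
#' @param frequency Frequency slice, Hz.
#' @param threshold Level in dB above which points are averaged.
#' @return Named numeric `c(azimuth, elevation)` in degrees.
#' @export
near_peak_mean_direction <- function(beam, frequency = beam$frequency[1],
                                     threshold = -1) {
  i <- match(frequency, beam$frequency)
  if (is.na(i)) stop("frequency not present in beam pattern")
  keep <- beam$db[, i] >= threshold
  u <- colMeans(beam$grid$units[keep, , drop = FALSE])
  ae <- unit_to_sph(u)
  c(azimuth = ae$azimuth, elevation = ae$elevation)
}
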