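# Iterative beam-axis alignment and averaging. Each click's microphone
# directions are iteratively shifted (and optionally rotated about the map
# origin) until the center of the best-fitting ellipse to its -3 dB contour
# at the reference frequency falls on the origin; aligned clicks are then
# merged in 10-degree azimuth-elevation bins and interpolated into an
# average beam pattern, separately for left- and right-pointing clicks.

#' Align one click's beam axis to the origin
#'
#' Repeats reconstruct -> fit ellipse at the reference frequency -> shift
#' every microphone direction by minus the ellipse center, until the center
#' magnitude drops below `tol` or `max_iter` is reached. With
#' `rotate = TRUE` each iteration additionally rotates the projected
#' coordinates about the origin to undo drift of the ellipse's major-axis
#' angle between iterations (the default is pure shifting).
#'
#' @param samples Data frame with per-microphone `azimuth`, `elevation`
#'   (degrees) and `db` at the reference frequency (normalized or raw; only
#'   shape matters).
#' @param grid Reconstruction grid used during alignment.
#' @param tol Convergence tolerance on the ellipse-center magnitude, deg.
#' @param max_iter Maximum number of iterations.
#' @param damping Fraction of the ellipse center applied per shift; values
#'   below 1 suppress period-two oscillation for marginally sampled
#'   clicks.
#' @param rotate Logical; also rotate to stabilize the major-axis angle.
#' @return An `alignment_result`: the aligned samples, cumulative
#'   `shift` (azimuth, elevation), cumulative `rotation` (deg), iteration
#'   count and `converged` flag.
#' @export
align_click <- function(samples, grid = direction_grid(2, 2), tol = 0.5,
                        max_iter = 20, damping = 0.7, rotate = FALSE) {
  stopifnot(all(c("azimuth", "elevation", "db") %in% names(samples)))
  cur <- samples
  shift <- c(azimuth = 0, elevation = 0)
  rot_total <- 0
  last_angle <- NA_real_
  converged <- FALSE
  iters <- 0
  fit <- NULL
  boundary <- NA
  for (i in seq_len(max_iter)) {
    iters <- i
    rb <- rbf_interpolate(cur, grid)
    ct <- tryCatch(contour_minus3db(rb, rb$frequency[1]),
                   error = function(e) NULL)
    fit <- if (is.null(ct)) NULL else {
      tryCatch(fit_ellipse(ct), error = function(e) NULL)
    }
    if (is.null(fit)) break
    boundary <- attr(ct, "boundary")
    ctr <- fit$center
    if (sqrt(sum(ctr^2)) < tol) {
      converged <- TRUE
      # apply the final sub-tolerance center too: leaving it produces a
      # residual correlated with the approach direction across clicks
      w <- wrap_az_el(cur$azimuth - ctr[1], cur$elevation - ctr[2])
      cur$azimuth <- w$azimuth
      cur$elevation <- w$elevation
      shift <- shift - c(ctr[1], ctr[2])
      break
    }
    step <- damping * ctr
    w <- wrap_az_el(cur$azimuth - step[1], cur$elevation - step[2])
    cur$azimuth <- w$azimuth
    cur$elevation <- w$elevation
    shift <- shift - c(step[1], step[2])
    if (rotate) {
      if (!is.na(last_angle)) {
        dphi <- fit$rotation - last_angle
        p <- eckert4(cur$azimuth, cur$elevation)
        cs <- cos(deg2rad(-dphi)); sn <- sin(deg2rad(-dphi))
        back <- eckert4_inverse(cs * p$x - sn * p$y, sn * p$x + cs * p$y)
        cur$azimuth <- back$azimuth
        cur$elevation <- back$elevation
        rot_total <- rot_total - dphi
      }
      last_angle <- fit$rotation
    }
  }
  structure(
    list(
      samples = tibble::as_tibble(cur),
      shift = shift, rotation = rot_total,
      iterations = iters, converged = converged,
      fit = fit, boundary = boundary
    ),
    class = "alignment_result"
  )
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(
    "<alignment_result> shift (%.2f, %.2f) deg, %d iterations, %s\n",
    x$shift[1], x$shift[2], x$iterations,
    if (x$converged) "converged" else "NOT converged"
  ))
  invisible(x)
}

#' @method tidy alignment_result
#' @export
tidy.alignment_result <- function(x, ...) {
  tibble::tibble(
    azimuth_shift = x$shift[1], elevation_shift = x$shift[2],
    rotation = x$rotation, iterations = x$iterations,
    converged = x$converged
  )
}

#' Merge aligned clicks into an average beam pattern
#'
#' Pools the aligned, per-click-normalized microphone samples of one side,
#' averages them in `bin`-degree azimuth-elevation bins (bins with no
#' samples stay missing - they are never zero-filled), interpolates the bin
#' means with the same spherical RBF used for individual clicks, and
#' renormalizes to 0 dB.
#'
#' @param clicks A list of aligned sample tables (each with `azimuth`,
#'   `elevation`, `db`), or a single data frame with a `click` column.
#' @param bin Bin width in degrees (default 10).
#' @param grid Output grid for the interpolated average surface.
#' @param frequency Optional frequency label, Hz.
#' @return An `average_beam`: a `beam_pattern` plus the bin table
#'   (`bins`: bin centers, mean dB, click/sample count).
#' @export
merge_average <- function(clicks, bin = 10, grid = direction_grid(),
                          frequency = NA_real_) {
  if (is.data.frame(clicks)) {
    stopifnot("click" %in% names(clicks))
    pooled <- tibble::as_tibble(clicks)
  } else {
    if (length(clicks) < 1) stop("no clicks to average")
    pooled <- dplyr::bind_rows(
      purrr::imap(clicks, function(s, i) dplyr::mutate(s, click = i))
    )
  }
  # normalize each click to its loudest sample before pooling
  pooled <- pooled |>
    dplyr::group_by(.data$click) |>
    dplyr::mutate(db = .data$db - max(.data$db)) |>
    dplyr::ungroup()

  bins <- pooled |>
    dplyr::mutate(
      az_bin = floor(.data$azimuth / bin) * bin + bin / 2,
      el_bin = floor(.data$elevation / bin) * bin + bin / 2
    ) |>
    dplyr::group_by(.data$az_bin, .data$el_bin) |>
    dplyr::summarise(
      db = mean(.data$db),
      n_samples = dplyr::n(),
      n_clicks = dplyr::n_distinct(.data$click),
      .groups = "drop"
    )
  if (nrow(bins) < 5) stop("too few occupied bins to build an average beam")

  rb <- rbf_interpolate(
    tibble::tibble(azimuth = bins$az_bin, elevation = bins$el_bin,
                   db = bins$db),
    grid, frequency
  )
  rb$bins <- bins
  rb$metadata$model <- "average_beam"
  class(rb) <- c("average_beam", class(rb))
  rb
}

#' Beam metrics across frequency
#'
#' Per-frequency beam center, -3 dB azimuth/elevation widths and aspect
#' ratio of a (multi-frequency) beam pattern, with the beam-center azimuth
#' optionally referenced to the value at 35 kHz.
#'
#' @param beam A multi-frequency `beam_pattern`.
#' @param frequencies Frequencies to evaluate (default: all in `beam`).
#' @param reference_frequency If not `NULL`, subtract this frequency's
#'   center from the center columns (the 35 kHz alignment convention).
#' @return A tibble with one row per frequency: `center_azimuth`,
#'   `center_elevation`, `az_extent`, `el_extent`, `aspect_ratio`.
#' @export
beam_metrics <- function(beam, frequencies = beam$frequency,
                         reference_frequency = NULL) {
  rows <- purrr::map(frequencies, function(f) {
    fit <- fit_ellipse(contour_minus3db(beam, f))
    tibble::tibble(
      frequency = f,
      center_azimuth = fit$center[1],
      center_elevation = fit$center[2],
      az_extent = fit$az_extent,
      el_extent = fit$el_extent,
      aspect_ratio = fit$aspect_ratio
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(reference_frequency)) {
    i <- which.min(abs(out$frequency - reference_frequency))
    out$center_azimuth <- out$center_azimuth - out$center_azimuth[i]
    out$center_elevation <- out$center_elevation - out$center_elevation[i]
  }
  out
}
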