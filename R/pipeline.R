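# End-to-end reconstruction: from a recording bundle (real or synthetic)
# to average left/right beam patterns. Per click: estimate the head pose
# (markers, falling back to the trajectory tangent), project microphones
# into the bat frame, compensate ESDs, screen with the sampling-quality
# criteria, align the 35 kHz beam axis to the origin, then merge aligned
# clicks per side into 10-degree-binned average patterns across frequency.

#' Estimate the head pose for one click of a bundle
#'
#' Uses the three head markers at the motion-capture frame nearest the
#' click time; if any marker is missing there, falls back to the
#' horizontal trajectory tangent with a vertical head normal.
#'
#' @param bundle An `experiment_bundle`.
#' @param click_id Click identifier.
#' @return A `bat_pose` (its `source` records which path was used).
#' @export
click_pose <- function(bundle, click_id) {
  t <- bundle$clicks$time[match(click_id, bundle$clicks$click)]
  frame_t <- bundle$trajectory$time[which.min(abs(bundle$trajectory$time - t))]
  mk <- dplyr::filter(bundle$markers, .data$time == frame_t)
  get <- function(name) {
    r <- mk[mk$marker == name, ]
    c(r$x[1], r$y[1], r$z[1])
  }
  a <- get("a"); b <- get("b"); cc <- get("c")
  if (!anyNA(c(a, b, cc))) {
    head_pose_from_markers(a, b, cc)
  } else {
    head_pose_fallback(bundle$trajectory[, c("time", "x", "y", "z")], t)
  }
}

# compensated per-mic levels for one click, all frequencies (flat mics)
compensated_click_table <- function(bundle, click_id, pose) {
  proj <- project_mics_to_bat_frame(bundle$mics, pose)
  esd <- dplyr::filter(bundle$esd, .data$click == click_id)
  cfg <- bundle$config
  out <- dplyr::left_join(
    dplyr::select(esd, "mic", "frequency", "esd"),
    dplyr::select(proj, "mic", "azimuth", "elevation", "range"),
    by = "mic"
  )
  alpha <- atmospheric_absorption(out$frequency, cfg$medium)
  dplyr::mutate(
    out,
    db = .data$esd + 20 * log10(.data$range / cfg$r_ref) + alpha * .data$range
  )
}

#' Reconstruct and average a whole session
#'
#' Runs the full pipeline on a bundle: pose estimation, ESD compensation,
#' quality screening, iterative 35 kHz beam-axis alignment, and per-side
#' binned averaging across all frequencies.
#'
#' @param bundle An `experiment_bundle` (from [make_session()] or read
#'   from disk).
#' @param criteria Quality thresholds, see [quality_criteria()].
#' @param ref_frequency Alignment reference frequency, Hz (35 kHz as the
#'   standard choice).
#' @param align_grid Grid used during alignment iterations (coarser is
#'   faster; ellipse centers are sub-grid accurate).
#' @param grid Final reconstruction grid for the average patterns.
#' @param bin Averaging bin width, degrees.
#' @param tol,max_iter Alignment convergence controls.
#' @return A `session_recon`: per-click summary tibble (`clicks`), the
#'   per-side multi-frequency average `beams`, and per-side bin tables.
#' @export
reconstruct_session <- function(bundle, criteria = quality_criteria(),
                                ref_frequency = 35e3,
                                align_grid = direction_grid(2, 2),
                                grid = direction_grid(), bin = 10,
                                tol = 0.5, max_iter = 20) {
  cfg <- bundle$config
  if (!ref_frequency %in% cfg$frequencies) {
    stop("reference frequency not among the bundle's frequencies")
  }
  click_rows <- list()
  aligned <- list()
  for (i in seq_len(nrow(bundle$clicks))) {
    cid <- bundle$clicks$click[i]
    pose <- click_pose(bundle, cid)
    tab <- compensated_click_table(bundle, cid, pose)
    ref <- dplyr::filter(tab, .data$frequency == ref_frequency)
    qual <- quality_filter(
      tibble::tibble(azimuth = ref$azimuth, elevation = ref$elevation,
                     db = ref$esd),
      criteria
    )
    row <- tibble::tibble(
      click = cid, side = bundle$clicks$side[i], pose_source = pose$source,
      quality_pass = qual$pass, converged = NA,
      azimuth_shift = NA_real_, elevation_shift = NA_real_
    )
    if (qual$pass) {
      samples <- tibble::tibble(
        azimuth = ref$azimuth, elevation = ref$elevation,
        db = ref$db - max(ref$db)
      )
      al <- align_click(samples, align_grid, tol = tol, max_iter = max_iter)
      # final-fit sanity: discard clicks whose aligned main lobe is clipped
      # by the grid edge or degenerate (the iteration can lock onto an
      # interpolation artifact for marginally sampled clicks)
      sane <- !is.null(al$fit) && isFALSE(al$boundary) &&
        min(al$fit$az_extent, al$fit$el_extent) >= 8 &&
        max(al$fit$az_extent, al$fit$el_extent) <= 120
      row$converged <- al$converged && sane
      row$azimuth_shift <- al$shift[1]
      row$elevation_shift <- al$shift[2]
      if (al$converged && sane) {
        w <- wrap_az_el(tab$azimuth + al$shift[1],
                        tab$elevation + al$shift[2])
        aligned[[length(aligned) + 1]] <- tab |>
          dplyr::mutate(
            azimuth = w$azimuth, elevation = w$elevation,
            click = cid, side = bundle$clicks$side[i]
          )
      }
    }
    click_rows[[i]] <- row
  }
  clicks <- dplyr::bind_rows(click_rows)
  pool <- dplyr::bind_rows(aligned)
  if (nrow(pool) == 0) stop("no clicks survived quality screening and alignment")

  sides <- list()
  for (sd in unique(pool$side)) {
    sub <- dplyr::filter(pool, .data$side == sd)
    per_freq <- purrr::map(cfg$frequencies, function(f) {
      fs <- dplyr::filter(sub, .data$frequency == f)
      merge_average(
        tibble::tibble(azimuth = fs$azimuth, elevation = fs$elevation,
                       db = fs$db, click = fs$click),
        bin = bin, grid = grid, frequency = f
      )
    })
    db <- do.call(cbind, purrr::map(per_freq, function(b) b$db[, 1]))
    beam <- new_beam_pattern(db, grid, cfg$frequencies,
                             metadata = list(model = "average_beam", side = sd))
    beam$bins <- purrr::map(per_freq, "bins")
    beam$anchors <- dplyr::bind_rows(purrr::map2(
      per_freq, cfg$frequencies, function(b, f) {
        i <- which.max(b$bins$db)
        tibble::tibble(frequency = f, azimuth = b$bins$az_bin[i],
                       elevation = b$bins$el_bin[i])
      }
    ))
    sides[[sd]] <- beam
  }

  structure(
    list(clicks = clicks, beams = sides, aligned = pool, config = cfg,
         ref_frequency = ref_frequency, bin = bin, grid = grid),
    class = "session_recon"
  )
}

#' Pooled average beam across both click sides
#'
#' Mirrors the right-pointing clicks' aligned samples across the midline
#' and merges them with the left-pointing clicks before binned averaging.
#' When left and right clicks are mirror images of a single underlying
#' beam (as in the synthetic sessions), this pools all clicks into one
#' estimate of that beam and halves the estimator variance relative to a
#' per-side average.
#'
#' @param recon A [reconstruct_session()] result.
#' @param frequency Frequency, Hz.
#' @param bin Bin width, degrees.
#' @param grid Output grid.
#' @return An `average_beam` at `frequency`.
#' @export
pooled_average <- function(recon, frequency = recon$ref_frequency,
                           bin = recon$bin, grid = recon$grid) {
  sub <- dplyr::filter(recon$aligned, .data$frequency == !!frequency)
  if (nrow(sub) == 0) stop("no aligned samples at this frequency")
  sub$azimuth <- ifelse(sub$side == "right", -sub$azimuth, sub$azimuth)
  merge_average(
    tibble::tibble(azimuth = sub$azimuth, elevation = sub$elevation,
                   db = sub$db, click = sub$click),
    bin = bin, grid = grid, frequency = frequency
  )
}

#' @export
print.session_recon <- function(x, ...) {
  cat(sprintf(
    "<session_recon> %d clicks (%d aligned), sides: %s\n",
    nrow(x$clicks), sum(x$clicks$converged %in% TRUE),
    paste(names(x$beams), collapse = ", ")
  ))
  invisible(x)
}

#' @method tidy session_recon
#' @export
tidy.session_recon <- function(x, ...) x$clicks

#' @method glance session_recon
#' @export
glance.session_recon <- function(x, ...) {
  tibble::tibble(
    n_clicks = nrow(x$clicks),
    n_quality_pass = sum(x$clicks$quality_pass),
    n_aligned = sum(x$clicks$converged %in% TRUE),
    frac_marker_pose = mean(x$clicks$pose_source == "markers"),
    ref_frequency = x$ref_frequency
  )
}
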