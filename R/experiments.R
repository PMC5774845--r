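# Scripted computational experiments: tongue-steering sweeps, model
# sensitivity analyses, Monte Carlo validation of the measurement pipeline
# against spatial-sampling bias, and statistical model-vs-data comparison.

#' Default transmission-array configuration
#'
#' The canonical one-sided left array on the simplified head, with a
#' tongue position inside the mouth cavity: the configuration used by the
#' steering and sensitivity experiments unless overridden.
#'
#' @param mesh Optional pre-built head mesh (built at 1 mm seam resolution
#'   if omitted).
#' @param n_elements Number of discrete elements.
#' @param arc_range Fractional window of the lip seam holding the
#'   elements; the default occupies the caudal three quarters (the
#'   forward-array variant uses `c(0, 0.75)`).
#' @return A list with `mesh`, `array`, `tongue` and the canonical tongue
#'   displacement direction `steer_direction` used by the steering sweep.
#' @export
default_array_config <- function(mesh = NULL, n_elements = 8,
                                 arc_range = c(0.25, 1)) {
  if (is.null(mesh)) mesh <- build_simplified_head(edge_target = 1)
  array <- place_elements(mesh, "left", "discrete", n = n_elements,
                          arc_range = arc_range)
  tongue <- tongue_position(c(10, 2, -3), side = "left", mesh = mesh)
  list(mesh = mesh, array = array, tongue = tongue,
       steer_direction = c(1, -1, 0) / sqrt(2))
}

#' Tongue-position steering sweep
#'
#' Evaluates the transmission-array model for a series of tongue clicking
#' positions and extracts the beam-center azimuth at the given frequency.
#' A single tongue-location change steers the beam; the sweep extent
#' quantifies how far.
#'
#' @param array An [place_elements()] spec.
#' @param tongue_positions List of [tongue_position()] objects (>= 2), or
#'   a numeric vector of displacements in mm applied to `base_tongue`
#'   along `direction`.
#' @param base_tongue,direction Base tongue position and unit displacement
#'   direction used when `tongue_positions` is numeric.
#' @param frequency Evaluation frequency, Hz.
#' @param mesh Head mesh (required for `method = "bem"`).
#' @param method `"freefield"` (fast mode) or `"bem"`.
#' @param medium,grid Passed to the beam model.
#' @return A `steering_curve` tibble: `displacement`, `center_azimuth`,
#'   `center_elevation`; attributes `extent` (deg) and `monotone`.
#' @export
steering_sweep <- function(array, tongue_positions, base_tongue = NULL,
                           direction = c(1, 0, 0), frequency = 35e3,
                           mesh = NULL, method = c("freefield", "bem"),
                           medium = acoustic_medium(),
                           grid = direction_grid()) {
  method <- match.arg(method)
  if (is.numeric(tongue_positions)) {
    stopifnot(!is.null(base_tongue))
    direction <- direction / sqrt(sum(direction^2))
    disp <- tongue_positions
    tongue_positions <- lapply(disp, function(d) {
      tongue_position(base_tongue$location + d * direction, base_tongue$side)
    })
  } else {
    p0 <- tongue_positions[[1]]$location
    disp <- vapply(tongue_positions, function(tp) {
      sqrt(sum((tp$location - p0)^2))
    }, numeric(1))
  }
  if (length(tongue_positions) < 2) stop("need at least 2 tongue positions")

  centers <- purrr::map(tongue_positions, function(tp) {
    beam <- transmission_array_beam(array, tp, frequency, mesh = mesh,
                                    method = method, medium = medium,
                                    grid = grid)
    beam_center(beam, frequency)
  })
  out <- tibble::tibble(
    displacement = disp,
    center_azimuth = vapply(centers, `[`, numeric(1), 1),
    center_elevation = vapply(centers, `[`, numeric(1), 2)
  )
  d <- diff(out$center_azimuth)
  attr(out, "extent") <- diff(range(out$center_azimuth))
  attr(out, "monotone") <- all(d >= -1e-9) || all(d <= 1e-9)
  class(out) <- c("steering_curve", class(out))
  out
}

#' Sensitivity suite over model configuration variants
#'
#' Runs the transmission-array model across configuration variants -
#' discrete vs continuous one-sided apertures, a forward-shifted array, an
#' ears-removed head, and the two-sided symmetric aperture with a midline
#' tongue - and summarizes the diagnostic beam features of each: the
#' 35 kHz aspect ratio, the beam-center azimuth shift from the lowest to
#' the highest frequency, and its monotonicity.
#'
#' @param mesh Head mesh; built at 1 mm resolution if omitted.
#' @param frequencies Frequencies, Hz.
#' @param n_elements Elements per side.
#' @param grid Evaluation grid.
#' @param medium An [acoustic_medium()].
#' @return A tibble with one row per variant: `aspect_ratio`,
#'   `center_shift` (deg, low minus high frequency azimuth),
#'   `monotone_center`, `max_abs_center_azimuth`.
#' @export
sensitivity_suite <- function(mesh = NULL,
                              frequencies = seq(25e3, 55e3, by = 10e3),
                              n_elements = 8, grid = direction_grid(),
                              medium = acoustic_medium()) {
  if (is.null(mesh)) mesh <- build_simplified_head(edge_target = 1)
  mesh_noears <- build_simplified_head(
    edge_target = mesh$params$edge_target %||% 1, ears = FALSE
  )
  tongue <- tongue_position(c(10, 2, -3), side = "left", mesh = mesh)
  tongue_mid <- tongue_position(c(10, 0, -3), mesh = mesh)
  arc <- c(0.25, 1)

  variants <- list(
    discrete = list(mesh = mesh,
                    array = place_elements(mesh, "left", "discrete",
                                           n = n_elements, arc_range = arc)),
    continuous = list(mesh = mesh,
                      array = place_elements(mesh, "left", "continuous",
                                             spacing = 1, arc_range = arc)),
    forward = list(mesh = mesh,
                   array = place_elements(mesh, "left", "discrete",
                                          n = n_elements,
                                          arc_range = c(0, 0.75))),
    no_ears = list(mesh = mesh_noears,
                   array = place_elements(mesh_noears, "left", "discrete",
                                          n = n_elements, arc_range = arc)),
    two_sided = list(mesh = mesh,
                     array = place_elements(mesh, "both", "discrete",
                                            n = n_elements, arc_range = arc))
  )

  rows <- purrr::imap(variants, function(v, nm) {
    tp <- if (nm == "two_sided") tongue_mid else tongue
    beam <- transmission_array_beam(v$array, tp, frequencies, grid = grid,
                                    medium = medium)
    met <- beam_metrics(beam)
    d <- diff(met$center_azimuth)
    tibble::tibble(
      variant = nm,
      aspect_ratio = met$aspect_ratio[which.min(abs(met$frequency - 35e3))],
      center_shift = met$center_azimuth[1] -
        met$center_azimuth[nrow(met)],
      monotone_center = all(d >= -1e-9) || all(d <= 1e-9),
      max_abs_center_azimuth = max(abs(met$center_azimuth))
    )
  })
  dplyr::bind_rows(rows)
}

#' Monte Carlo validation of the measurement pipeline
#'
#' Generates a full synthetic session whose clicks are drawn from a set of
#' truth beam models (optionally with randomized beam directions), runs
#' the complete reconstruction-alignment-averaging pipeline, and compares
#' the recovered average-beam features (35 kHz beam center, aspect ratio,
#' center-vs-frequency curve) with the truth models' own features. This
#' probes whether spatial under-sampling by the microphone array and
#' measurement noise bias the reconstructed beam.
#'
#' @param truth_models A `truth_model` or list of them (selected per
#'   click at random).
#' @param config A [session_config()] (its `truth` field is overridden).
#' @param grid Final reconstruction grid.
#' @param ... Passed to [reconstruct_session()].
#' @return A `mc_validation` list: the `session_recon`, per-side recovered
#'   metrics, truth metrics per model, and per-side recovery errors.
#' @export
monte_carlo_validation <- function(truth_models, config = session_config(),
                                   grid = direction_grid(), ...) {
  config$truth <- truth_models
  bundle <- make_session(config)
  recon <- reconstruct_session(bundle, grid = grid, ...)

  truth_set <- if (inherits(truth_models, "truth_model")) list(truth_models)
  else truth_models
  truth_metrics <- purrr::map(truth_set, function(m) {
    beam <- truth_beam(m, config$frequencies, grid)
    beam_metrics(beam, reference_frequency = 35e3) |>
      dplyr::mutate(model = m$label)
  }) |> dplyr::bind_rows()

  recon_metrics <- purrr::imap(recon$beams, function(b, sd) {
    beam_metrics(b) |> dplyr::mutate(side = sd)
  }) |> dplyr::bind_rows()

  # pooled (left + mirrored right) recovery of the underlying beam
  pooled_metrics <- purrr::map(config$frequencies, function(f) {
    avg <- pooled_average(recon, f)
    fit <- tryCatch(fit_ellipse(contour_minus3db(avg, f)),
                    error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    tibble::tibble(
      frequency = f,
      center_azimuth = fit$center[1], center_elevation = fit$center[2],
      az_extent = fit$az_extent, el_extent = fit$el_extent,
      aspect_ratio = fit$aspect_ratio
    )
  }) |> dplyr::bind_rows()

  structure(
    list(recon = recon, recon_metrics = recon_metrics,
         pooled_metrics = pooled_metrics,
         truth_metrics = truth_metrics, config = config),
    class = "mc_validation"
  )
}

#' @export
print.mc_validation <- function(x, ...) {
  cat("<mc_validation>\n")
  print(x$recon_metrics)
  invisible(x)
}

#' Individual-click ellipse features from a synthetic population
#'
#' Reconstructs each quality-passing click of a bundle individually at the
#' reference frequency and fits the -3 dB ellipse; used to build the
#' per-source feature distributions of [model_comparison()].
#'
#' @param bundle An `experiment_bundle`.
#' @param ref_frequency Hz.
#' @param grid Reconstruction grid.
#' @param criteria Quality thresholds.
#' @return A tibble: one row per usable click with `az_extent`,
#'   `el_extent`, `aspect_ratio`, `center_azimuth`, `center_elevation`.
#' @export
click_ellipse_features <- function(bundle, ref_frequency = 35e3,
                                   grid = direction_grid(2, 2),
                                   criteria = quality_criteria()) {
  rows <- list()
  for (i in seq_len(nrow(bundle$clicks))) {
    cid <- bundle$clicks$click[i]
    pose <- click_pose(bundle, cid)
    tab <- compensated_click_table(bundle, cid, pose)
    ref <- dplyr::filter(tab, .data$frequency == ref_frequency)
    qual <- quality_filter(
      tibble::tibble(azimuth = ref$azimuth, elevation = ref$elevation,
                     db = ref$esd), criteria
    )
    if (!qual$pass) next
    fit <- tryCatch({
      rb <- rbf_interpolate(
        tibble::tibble(azimuth = ref$azimuth, elevation = ref$elevation,
                       db = ref$db - max(ref$db)), grid
      )
      fit_ellipse(contour_minus3db(rb, rb$frequency[1]))
    }, error = function(e) NULL)
    if (is.null(fit)) next
    rows[[length(rows) + 1]] <- tibble::tibble(
      click = cid, side = bundle$clicks$side[i],
      az_extent = fit$az_extent, el_extent = fit$el_extent,
      aspect_ratio = fit$aspect_ratio,
      center_azimuth = fit$center[1], center_elevation = fit$center[2]
    )
  }
  dplyr::bind_rows(rows)
}

#' Statistical comparison of beam-shape distributions across sources
#'
#' Builds per-click -3 dB ellipse feature distributions for three sources
#' - a "data-like" arm (transmission-array truth plus measurement noise),
#' the transmission-array model arm, and the piston model arm - and
#' compares their aspect ratios pairwise with the Mann-Whitney rank-sum
#' test. The data arm here is itself synthetic (higher noise), so the
#' comparison machinery runs without recordings.
#'
#' @param array_truth,piston_truth Truth models for the two model arms.
#' @param n_pairs Click pairs per arm.
#' @param data_noise_sd,model_noise_sd Noise (dB) for the data-like and
#'   model arms.
#' @param seed Base seed (each arm uses an offset of it).
#' @param config_fun Optional function modifying each arm's
#'   [session_config()].
#' @return A `comparison_report`: `features` tibble (per source), `tests`
#'   tibble of pairwise rank-sum results.
#' @export
model_comparison <- function(array_truth, piston_truth = truth_piston(),
                             n_pairs = 15, data_noise_sd = 2,
                             model_noise_sd = 0.5, seed = 1,
                             config_fun = identity) {
  arms <- list(
    data = list(truth = array_truth, noise = data_noise_sd, seed = seed),
    array_model = list(truth = array_truth, noise = model_noise_sd,
                       seed = seed + 1000),
    piston_model = list(truth = piston_truth, noise = model_noise_sd,
                        seed = seed + 2000)
  )
  features <- purrr::imap(arms, function(a, nm) {
    cfg <- config_fun(session_config(
      seed = a$seed, n_pairs = n_pairs, noise_sd = a$noise, truth = a$truth,
      dropout_prob = 0
    ))
    bundle <- make_session(cfg)
    click_ellipse_features(bundle) |> dplyr::mutate(source = nm)
  }) |> dplyr::bind_rows()

  pairs <- utils::combn(unique(features$source), 2, simplify = FALSE)
  tests <- purrr::map(pairs, function(p) {
    x <- features$aspect_ratio[features$source == p[1]]
    y <- features$aspect_ratio[features$source == p[2]]
    tt <- rank_sum_test(x, y)
    tibble::tibble(source1 = p[1], source2 = p[2],
                   U = tt$statistic, p.value = tt$p.value)
  }) |> dplyr::bind_rows()

  structure(list(features = features, tests = tests),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  print(
    x$features |>
      dplyr::group_by(.data$source) |>
      dplyr::summarise(
        n = dplyr::n(),
        mean_aspect = mean(.data$aspect_ratio),
        mean_az_extent = mean(.data$az_extent),
        mean_el_extent = mean(.data$el_extent)
      )
  )
  print(x$tests)
  invisible(x)
}

#' @method tidy comparison_report
#' @export
tidy.comparison_report <- function(x, ...) x$tests

#' @method glance comparison_report
#' @export
glance.comparison_report <- function(x, ...) {
  x$features |>
    dplyr::group_by(.data$source) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_aspect = mean(.data$aspect_ratio),
      sd_aspect = stats::sd(.data$aspect_ratio),
      .groups = "drop"
    )
}
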