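# Synthetic flight-room experiments. A session emulates the measurement:
# 34 microphones on the walls of a 2.3 x 2.3 x 2.4 m room, a smooth flight
# trajectory carrying three head markers (with dropout), click pairs about
# 20 ms apart whose left/right beams alternate with inter-click angles up
# to 60 degrees, and per-microphone energy spectral densities sampled from
# a ground-truth beam model with spherical spreading, atmospheric
# absorption and additive Gaussian measurement noise in dB. Everything is
# reproducible from the session seed.

#' Session configuration for the synthetic experiment generator
#'
#' @param seed Integer seed fixing all randomness of the session.
#' @param room_dim Room dimensions (x, y, z), metres.
#' @param n_mics Number of microphones (placed on walls and ceiling).
#' @param n_pairs Number of click pairs along the trajectory.
#' @param pair_interval Time between successive pairs, s.
#' @param intra_pair_interval Time between the two clicks of a pair, s
#'   (about 20 ms).
#' @param angle_range Range of the per-pair inter-click angle, degrees;
#'   drawn uniformly and split symmetrically about the head aim.
#' @param noise_sd Standard deviation of the additive measurement noise,
#'   dB.
#' @param dropout_prob Per-marker, per-click probability that a head
#'   marker is not captured (forcing the trajectory-fallback pose).
#' @param frequencies Analysis frequencies, Hz.
#' @param source_level Source level at the reference range, dB.
#' @param truth A truth model ([truth_gaussian()], [truth_piston()],
#'   [truth_array()]), or a list of them sampled per click.
#' @param medium An [acoustic_medium()].
#' @param r_ref Reference range for spreading compensation, metres.
#' @return A `session_config` list.
#' @export
session_config <- function(seed = 1, room_dim = c(2.3, 2.3, 2.4),
                           n_mics = 34, n_pairs = 100, pair_interval = 0.1,
                           intra_pair_interval = 0.020,
                           angle_range = c(20, 60), noise_sd = 1,
                           dropout_prob = 0.05,
                           frequencies = seq(25e3, 55e3, by = 5e3),
                           source_level = 100,
                           truth = truth_gaussian(),
                           medium = acoustic_medium(), r_ref = 0.1) {
  stopifnot(
    length(room_dim) == 3, all(room_dim > 0), n_mics >= 4, n_pairs >= 1,
    angle_range[1] >= 0, angle_range[2] <= 60,
    angle_range[1] <= angle_range[2],
    noise_sd >= 0, dropout_prob >= 0, dropout_prob <= 1
  )
  structure(
    list(
      seed = seed, room_dim = room_dim, n_mics = n_mics, n_pairs = n_pairs,
      pair_interval = pair_interval,
      intra_pair_interval = intra_pair_interval,
      angle_range = angle_range, noise_sd = noise_sd,
      dropout_prob = dropout_prob, frequencies = frequencies,
      source_level = source_level, truth = truth, medium = medium,
      r_ref = r_ref
    ),
    class = "session_config"
  )
}

# --- truth beam models -------------------------------------------------------

new_truth_model <- function(fun, label, params = list()) {
  structure(list(fun = fun, label = label, params = params),
            class = "truth_model")
}

#' @export
print.truth_model <- function(x, ...) {
  cat(sprintf("<truth_model> %s\n", x$label))
  invisible(x)
}

#' Evaluate a truth model at directions
#'
#' @param model A truth model.
#' @param azimuth,elevation Degrees.
#' @param frequency Hz.
#' @return Normalized dB values (0 dB at the model's per-frequency peak).
#' @export
truth_db <- function(model, azimuth, elevation, frequency) {
  model$fun(azimuth, elevation, frequency)
}

#' Analytic anisotropic Gaussian truth beam
#'
#' A fast fixture: Gaussian fall-off in azimuth and elevation with
#' prescribed -3 dB widths (so its best-fitting -3 dB ellipse has exactly
#' those angular extents), independent of frequency unless widths are
#' given as functions of frequency.
#'
#' @param az_width,el_width -3 dB full widths, degrees (constants or
#'   functions of frequency in Hz).
#' @param center Beam center `c(azimuth, elevation)`, degrees.
#' @param floor Sidelobe floor in dB: off-beam energy levels out here, as
#'   a real click's sidelobe/noise floor does.
#' @return A `truth_model`.
#' @export
truth_gaussian <- function(az_width = 25, el_width = 36, center = c(0, 0),
                           floor = -60) {
  aw <- if (is.function(az_width)) az_width else function(f) az_width
  ew <- if (is.function(el_width)) el_width else function(f) el_width
  new_truth_model(
    function(azimuth, elevation, frequency) {
      pmax(
        -3 * ((azimuth - center[1]) / (aw(frequency) / 2))^2 -
          3 * ((elevation - center[2]) / (ew(frequency) / 2))^2,
        floor
      )
    },
    label = "gaussian",
    params = list(az_width = az_width, el_width = el_width, center = center,
                  floor = floor)
  )
}

#' Circular-piston truth beam
#'
#' @param radius Piston radius, metres.
#' @param medium An [acoustic_medium()].
#' @param axis Piston axis unit vector.
#' @return A `truth_model` wrapping the closed-form piston directivity.
#' @export
truth_piston <- function(radius = 0.004, medium = acoustic_medium(),
                         axis = c(1, 0, 0)) {
  axis <- axis / sqrt(sum(axis^2))
  new_truth_model(
    function(azimuth, elevation, frequency) {
      u <- sph_to_unit(azimuth, elevation)
      ct <- pmin(1, pmax(-1, drop(u %*% axis)))
      x <- wavenumber(frequency, medium) * radius * sqrt(1 - ct^2)
      d <- ifelse(x < 1e-12, 1, 2 * besselJ(x, 1) / pmax(x, 1e-300))
      pmax(20 * log10(pmax(abs(d), 10^(DB_FLOOR / 20))), DB_FLOOR)
    },
    label = "piston", params = list(radius = radius)
  )
}

#' Free-field transmission-array truth beam
#'
#' Evaluates the tongue-driven phased-array model exactly at arbitrary
#' directions; the per-frequency normalization constant is found on a
#' 2-degree grid at construction time.
#'
#' @param array An [place_elements()] spec.
#' @param tongue A [tongue_position()].
#' @param frequencies Frequencies for which normalization is precomputed,
#'   Hz.
#' @param medium An [acoustic_medium()].
#' @param element_model Per-element source model (see
#'   [freefield_array_beam()]); default `"baffled"`.
#' @return A `truth_model`.
#' @export
truth_array <- function(array, tongue,
                        frequencies = seq(25e3, 55e3, by = 5e3),
                        medium = acoustic_medium(),
                        element_model = "baffled") {
  r_m <- element_ranges(tongue, array) / 1000
  pos_m <- array$positions / 1000
  use_baffle <- identical(element_model, "baffled") && !is.null(array$normals)
  raw_db <- function(units, f) {
    k <- wavenumber(f, medium)
    amp <- if (use_baffle) (1 + units %*% t(array$normals)) / 2 else 1
    ph <- exp(1i * k * (matrix(r_m, nrow(units), length(r_m), byrow = TRUE) -
                          units %*% t(pos_m)))
    p <- rowSums(amp * ph)
    pmax(20 * log10(pmax(Mod(p), 10^(DB_FLOOR / 20))), DB_FLOOR)
  }
  norm_grid <- direction_grid(2, 2)
  norms <- vapply(frequencies, function(f) max(raw_db(norm_grid$units, f)),
                  numeric(1))
  names(norms) <- as.character(frequencies)
  new_truth_model(
    function(azimuth, elevation, frequency) {
      u <- sph_to_unit(azimuth, elevation)
      nrm <- norms[as.character(frequency)]
      if (is.na(nrm)) nrm <- max(raw_db(direction_grid(2, 2)$units, frequency))
      raw_db(u, frequency) - nrm
    },
    label = "transmission_array",
    params = list(n_elements = array$n, side = array$side,
                  tongue = tongue$location)
  )
}

#' Evaluate a truth model as a beam pattern on a grid
#'
#' @param model A `truth_model`.
#' @param frequencies Frequencies, Hz.
#' @param grid A [direction_grid()].
#' @return A `beam_pattern`.
#' @export
truth_beam <- function(model, frequencies = seq(25e3, 55e3, by = 5e3),
                       grid = direction_grid()) {
  ae <- unit_to_sph(grid$units)
  db <- vapply(frequencies, function(f) {
    truth_db(model, ae$azimuth, ae$elevation, f)
  }, numeric(nrow(grid$units)))
  new_beam_pattern(db, grid, frequencies,
                   metadata = list(model = model$label))
}

#' Mirror a truth model across the midline
#'
#' Used to simulate right-pointing clicks from a left-pointing model.
#'
#' @param model A `truth_model`.
#' @return A `truth_model` with azimuth negated.
#' @export
mirror_truth <- function(model) {
  new_truth_model(
    function(azimuth, elevation, frequency) {
      model$fun(-azimuth, elevation, frequency)
    },
    label = paste0(model$label, "_mirror"), params = model$params
  )
}

# --- session components ------------------------------------------------------

#' Microphone array on the room walls
#'
#' Places `n_mics` microphones deterministically: dense square grids on the
#' two walls the flight corridor points toward (so the beam aim region is
#' densely sampled, as in the flight-room arrangement), the remainder on
#' the two rear walls, and two on the ceiling. All face the room center.
#'
#' @param room_dim Room dimensions, metres.
#' @param n_mics Number of microphones (default 34).
#' @param margin Inset from walls, metres.
#' @return A tibble with columns `mic`, `x`, `y`, `z`, `fx`, `fy`, `fz`.
#' @export
make_mic_array <- function(room_dim = c(2.3, 2.3, 2.4), n_mics = 34,
                           margin = 0.15) {
  lx <- room_dim[1]; ly <- room_dim[2]; lz <- room_dim[3]
  front_each <- min(16, (n_mics - 2) %/% 2)
  rear <- n_mics - 2 - 2 * front_each
  grid_uv <- function(n) {
    side <- ceiling(sqrt(n))
    g <- expand.grid(u = seq(0.12, 0.88, length.out = side),
                     v = seq(0.18, 0.92, length.out = side))
    g[seq_len(n), ]
  }
  gf <- grid_uv(front_each)
  pts <- rbind(
    cbind(lx - margin, gf$u * ly, gf$v * lz),   # far +x wall
    cbind(gf$u * lx, ly - margin, gf$v * lz)    # far +y wall
  )
  if (rear > 0) {
    gr <- grid_uv(rear)
    half <- ceiling(rear / 2)
    pts <- rbind(
      pts,
      cbind(margin, gr$u[seq_len(half)] * ly, gr$v[seq_len(half)] * lz),
      if (rear > half) {
        ii <- (half + 1):rear
        cbind(gr$u[ii] * lx, margin, gr$v[ii] * lz)
      }
    )
  }
  # remaining two on the corner edge between the front walls, at heights
  # straddling the wall grids (fills the azimuth gap along the diagonal)
  pts <- rbind(pts, cbind(lx - margin, ly - margin, c(0.40, 0.70) * lz))
  ctr <- room_dim / 2
  facing <- normalize_rows(matrix(ctr, nrow(pts), 3, byrow = TRUE) - pts)
  tibble::tibble(
    mic = seq_len(nrow(pts)),
    x = pts[, 1], y = pts[, 2], z = pts[, 3],
    fx = facing[, 1], fy = facing[, 2], fz = facing[, 3]
  )
}

# default head-stage marker offsets in the head frame (metres):
# front marker a, rear-left b, rear-right c
MARKER_OFFSETS <- rbind(
  a = c(0.020, 0.000, 0.005),
  b = c(-0.005, 0.010, 0.005),
  c = c(-0.005, -0.010, 0.005)
)

#' Smooth flight trajectory with head markers
#'
#' A C2 spline path through waypoints spanning the room, sampled at
#' `sample_rate`. The head frame at each sample has the aim along the
#' flight direction and the normal as close to vertical as orthogonality
#' allows; the three head-stage markers ride rigidly on that frame, and
#' each marker drops out independently with probability `dropout_prob`
#' (drawn from the current RNG state).
#'
#' @param room_dim Room dimensions, metres.
#' @param duration Flight duration, s.
#' @param sample_rate Motion-capture rate, Hz (default 200).
#' @param dropout_prob Per-marker per-frame dropout probability.
#' @param waypoints Optional n x 3 matrix of waypoints; a gentle S-shaped
#'   default crossing the room is used otherwise.
#' @return A list: `trajectory` (tibble time, x, y, z, plus head-frame
#'   vectors) and `markers` (long tibble time, marker, x, y, z with NA for
#'   dropped frames).
#' @export
make_trajectory <- function(room_dim = c(2.3, 2.3, 2.4), duration = 10,
                            sample_rate = 200, dropout_prob = 0,
                            waypoints = NULL) {
  if (is.null(waypoints)) {
    # a straight, level flight segment through the quadrant the microphone
    # array covers densely, at the height the wall grids are centred on:
    # the portion of a trial in which clicks are measurable
    waypoints <- cbind(
      seq(0.50, 1.35, length.out = 5) / 2.3 * room_dim[1],
      seq(0.50, 1.35, length.out = 5) / 2.3 * room_dim[2],
      rep(1.32, 5) / 2.4 * room_dim[3]
    )
  }
  tw <- seq(0, duration, length.out = nrow(waypoints))
  t <- seq(0, duration, by = 1 / sample_rate)
  fx <- stats::splinefun(tw, waypoints[, 1], method = "natural")
  fy <- stats::splinefun(tw, waypoints[, 2], method = "natural")
  fz <- stats::splinefun(tw, waypoints[, 3], method = "natural")
  pos <- cbind(fx(t), fy(t), fz(t))
  vel <- cbind(fx(t, deriv = 1), fy(t, deriv = 1), fz(t, deriv = 1))
  aim <- normalize_rows(vel)
  # head normal: vertical, orthogonalized against the aim
  up <- matrix(c(0, 0, 1), nrow(aim), 3, byrow = TRUE)
  nrm <- normalize_rows(up - aim * rowSums(up * aim))
  lft <- cbind(
    nrm[, 2] * aim[, 3] - nrm[, 3] * aim[, 2],
    nrm[, 3] * aim[, 1] - nrm[, 1] * aim[, 3],
    nrm[, 1] * aim[, 2] - nrm[, 2] * aim[, 1]
  )
  trajectory <- tibble::tibble(
    time = t, x = pos[, 1], y = pos[, 2], z = pos[, 3],
    aim_x = aim[, 1], aim_y = aim[, 2], aim_z = aim[, 3],
    norm_x = nrm[, 1], norm_y = nrm[, 2], norm_z = nrm[, 3]
  )
  markers <- purrr::map(rownames(MARKER_OFFSETS), function(mk) {
    off <- MARKER_OFFSETS[mk, ]
    mpos <- pos + off[1] * aim + off[2] * lft + off[3] * nrm
    drop_mask <- stats::runif(length(t)) < dropout_prob
    tibble::tibble(
      time = t, marker = mk,
      x = ifelse(drop_mask, NA_real_, mpos[, 1]),
      y = ifelse(drop_mask, NA_real_, mpos[, 2]),
      z = ifelse(drop_mask, NA_real_, mpos[, 3])
    )
  }) |> dplyr::bind_rows()
  list(trajectory = trajectory, markers = markers)
}

#' Click-pair train along a trajectory
#'
#' Pairs at regular intervals; within each pair the two clicks are
#' `intra_pair_interval` apart and point left then right, the pair's
#' inter-click angle being drawn uniformly from `angle_range` and split
#' symmetrically about the head aim.
#'
#' @param config A [session_config()].
#' @param trajectory Trajectory tibble from [make_trajectory()].
#' @return A tibble with one row per click: `click`, `pair`, `time`,
#'   `side`, `aim_offset` (degrees, positive = left).
#' @export
make_click_train <- function(config, trajectory) {
  t0 <- min(trajectory$time) + 0.1
  t_max <- max(trajectory$time) - 0.1
  starts <- t0 + (seq_len(config$n_pairs) - 1) * config$pair_interval
  if (any(starts + config$intra_pair_interval > t_max)) {
    stop("click train does not fit within the trajectory duration")
  }
  angles <- stats::runif(config$n_pairs, config$angle_range[1],
                         config$angle_range[2])
  tibble::tibble(
    click = seq_len(2 * config$n_pairs),
    pair = rep(seq_len(config$n_pairs), each = 2),
    time = as.vector(rbind(starts, starts + config$intra_pair_interval)),
    side = rep(c("left", "right"), config$n_pairs),
    aim_offset = as.vector(rbind(angles / 2, -angles / 2))
  )
}

# true head pose at an arbitrary time, from the trajectory head frame
pose_at_time <- function(trajectory, t) {
  i <- which.min(abs(trajectory$time - t))
  new_bat_pose(
    position = c(trajectory$x[i], trajectory$y[i], trajectory$z[i]),
    aim = c(trajectory$aim_x[i], trajectory$aim_y[i], trajectory$aim_z[i]),
    normal = c(trajectory$norm_x[i], trajectory$norm_y[i], trajectory$norm_z[i]),
    source = "truth"
  )
}

#' Synthesize per-microphone ESDs for one click
#'
#' Samples the truth beam at each microphone's direction in the click's
#' beam frame (head pose rotated by the aim offset), applies the source
#' level, spherical spreading, atmospheric absorption and microphone
#' response, and adds i.i.d. Gaussian noise in dB. The stored values are
#' raw received levels, so [compensate_esd()] inverts the propagation part
#' exactly.
#'
#' @param truth A `truth_model`.
#' @param pose The click's true head pose (a `bat_pose`).
#' @param aim_offset Azimuthal offset of the beam axis from the head aim,
#'   degrees.
#' @param mics Microphone tibble from [make_mic_array()].
#' @param config A [session_config()] (noise, frequencies, medium, source
#'   level).
#' @return A tibble with columns `mic`, `frequency`, `esd` (dB, raw),
#'   `azimuth`, `elevation`, `range` (true beam-frame geometry, kept for
#'   ground-truth bookkeeping).
#' @export
synthesize_esd <- function(truth, pose, aim_offset, mics, config) {
  beam_pose <- rotate_pose_azimuth(pose, aim_offset)
  proj <- project_mics_to_bat_frame(mics, beam_pose)
  flat <- mic_spec(0, c(0, 0, 0), c(1, 0, 0))
  rows <- tidyr::expand_grid(frequency = config$frequencies, mic = proj$mic) |>
    dplyr::left_join(
      dplyr::select(proj, "mic", "azimuth", "elevation", "range"),
      by = "mic"
    )
  tdb <- unlist(lapply(config$frequencies, function(f) {
    truth_db(truth, proj$azimuth, proj$elevation, f)
  }))
  raw <- apply_propagation(
    tdb + config$source_level, rows$frequency, flat, rep(rows$range, 1),
    medium = config$medium, r_ref = config$r_ref
  )
  noise <- stats::rnorm(nrow(rows), 0, config$noise_sd)
  dplyr::mutate(rows, esd = raw + noise, .before = "azimuth")
}

#' Generate a complete synthetic recording session
#'
#' Builds the microphone array, trajectory, marker tracks with dropout,
#' click train, and per-click per-microphone raw ESDs from the configured
#' truth model. All randomness derives from `config$seed`, so identical
#' configurations give identical bundles.
#'
#' @param config A [session_config()].
#' @return An `experiment_bundle`: `mics`, `trajectory`, `markers`,
#'   `clicks` (with the per-click truth model label), `esd` (long tibble),
#'   `truth`, `config`.
#' @export
make_session <- function(config = session_config()) {
  set.seed(config$seed)
  mics <- make_mic_array(config$room_dim, config$n_mics)
  duration <- config$n_pairs * config$pair_interval + 0.4
  traj <- make_trajectory(config$room_dim, duration,
                          dropout_prob = config$dropout_prob)
  clicks <- make_click_train(config, traj$trajectory)

  truth_set <- if (inherits(config$truth, "truth_model")) {
    list(config$truth)
  } else {
    config$truth
  }
  pick <- sample.int(length(truth_set), nrow(clicks), replace = TRUE)

  esd <- purrr::map(seq_len(nrow(clicks)), function(i) {
    pose <- pose_at_time(traj$trajectory, clicks$time[i])
    model <- truth_set[[pick[i]]]
    if (clicks$side[i] == "right") model <- mirror_truth(model)
    synthesize_esd(model, pose, clicks$aim_offset[i], mics, config) |>
      dplyr::mutate(click = clicks$click[i], .before = 1)
  }) |> dplyr::bind_rows()

  clicks$truth_model <- vapply(truth_set[pick], function(m) m$label,
                               character(1))
  structure(
    list(mics = mics, trajectory = traj$trajectory, markers = traj$markers,
         clicks = clicks, esd = esd, truth = truth_set, config = config),
    class = "experiment_bundle"
  )
}

#' @export
print.experiment_bundle <- function(x, ...) {
  cat(sprintf(
    "<experiment_bundle> %d mics, %d clicks, %d frequencies (seed %d)\n",
    nrow(x$mics), nrow(x$clicks), length(x$config$frequencies),
    x$config$seed
  ))
  invisible(x)
}

#' Write / read an experiment bundle as a directory of CSV + YAML files
#'
#' @param bundle An `experiment_bundle`.
#' @param path Directory path (created if needed).
#' @return `path` invisibly.
#' @export
write_bundle <- function(bundle, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("mics", "trajectory", "markers", "clicks", "esd")) {
    utils::write.csv(bundle[[nm]], file.path(path, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  cfg <- bundle$config
  cfg$truth <- NULL
  cfg$medium <- unclass(cfg$medium)
  yaml::write_yaml(
    c(unclass(cfg), list(truth_labels = vapply(bundle$truth, function(m) m$label,
                                               character(1)))),
    file.path(path, "session.yaml")
  )
  invisible(path)
}
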