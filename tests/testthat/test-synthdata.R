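test_that("the microphone array fills the room deterministically", {
  mics <- make_mic_array()
  expect_equal(nrow(mics), 34)
  room <- c(2.3, 2.3, 2.4)
  expect_true(all(mics$x >= 0 & mics$x <= room[1]))
  expect_true(all(mics$y >= 0 & mics$y <= room[2]))
  expect_true(all(mics$z >= 0 & mics$z <= room[3]))
  expect_identical(mics, make_mic_array())
  # facing vectors are unit and point inward
  expect_equal(mics$fx^2 + mics$fy^2 + mics$fz^2, rep(1, 34),
               tolerance = 1e-9)

  # angular coverage from the room centre: the mic directions subtend a
  # large solid angle (every direction probe within 60 degrees of a mic)
  ctr <- room / 2
  mdir <- lingualsonar:::normalize_rows(as.matrix(mics[, c("x", "y", "z")]) -
                           matrix(ctr, 34, 3, byrow = TRUE))
  probe <- direction_grid(10, 10)$units
  nearest <- apply(lingualsonar:::great_circle(probe, mdir), 1, min)
  frac <- mean(nearest <= deg2rad_test(60))
  expect_gte(frac * 4 * pi, 3 * pi)
})

test_that("trajectories carry recoverable marker frames", {
  set.seed(3)
  tr <- make_trajectory(duration = 4, dropout_prob = 0)
  expect_false(anyNA(tr$markers$x))
  # marker-derived pose matches the generating head frame
  i <- 300
  t_i <- tr$trajectory$time[i]
  get <- function(mk) {
    r <- tr$markers[tr$markers$marker == mk & tr$markers$time == t_i, ]
    c(r$x, r$y, r$z)
  }
  pose <- head_pose_from_markers(get("a"), get("b"), get("c"))
  expect_equal(pose$aim,
               unlist(tr$trajectory[i, c("aim_x", "aim_y", "aim_z")],
                      use.names = FALSE),
               tolerance = 1e-9)
  expect_equal(pose$normal,
               unlist(tr$trajectory[i, c("norm_x", "norm_y", "norm_z")],
                      use.names = FALSE),
               tolerance = 1e-9)

  # full dropout forces every pose to the trajectory fallback
  set.seed(3)
  tr2 <- make_trajectory(duration = 4, dropout_prob = 1)
  expect_true(all(is.na(tr2$markers$x)))
})

test_that("click trains alternate sides with the configured timing", {
  cfg <- session_config(n_pairs = 50)
  set.seed(1)
  tr <- make_trajectory(duration = cfg$n_pairs * cfg$pair_interval + 0.4)
  clicks <- make_click_train(cfg, tr$trajectory)
  expect_equal(nrow(clicks), 100)
  expect_identical(clicks$side, rep(c("left", "right"), 50))
  gaps <- clicks$time[clicks$side == "right"] -
    clicks$time[clicks$side == "left"]
  expect_equal(gaps, rep(0.020, 50))
  # within each pair the two clicks split the inter-click angle evenly
  expect_equal(clicks$aim_offset[clicks$side == "left"],
               -clicks$aim_offset[clicks$side == "right"])
  angles <- 2 * clicks$aim_offset[clicks$side == "left"]
  expect_true(all(angles >= 20 & angles <= 60))

  # sampling check: the mean inter-click angle approaches the configured
  # mean of the uniform(20, 60) distribution
  cfg2 <- session_config(n_pairs = 1000, pair_interval = 0.05)
  set.seed(99)
  tr2 <- make_trajectory(duration = cfg2$n_pairs * 0.05 + 0.4)
  big <- make_click_train(cfg2, tr2$trajectory)
  expect_lt(abs(mean(2 * big$aim_offset[big$side == "left"]) - 40), 1)
})

test_that("ESD synthesis round-trips through compensation at zero noise", {
  cfg <- session_config(seed = 5, noise_sd = 0, n_pairs = 2)
  mics <- make_mic_array()
  tr <- make_trajectory(duration = 1)
  pose <- lingualsonar:::pose_at_time(tr$trajectory, 0.5)
  truth <- truth_gaussian(25, 36)
  obs <- synthesize_esd(truth, pose, 12, mics, cfg)

  # compensating the raw levels recovers truth + source level exactly
  alpha <- atmospheric_absorption(obs$frequency, cfg$medium)
  comp <- obs$esd + 20 * log10(obs$range / cfg$r_ref) + alpha * obs$range
  tdb <- unlist(lapply(cfg$frequencies, function(f) {
    truth_db(truth, obs$azimuth[obs$frequency == f],
             obs$elevation[obs$frequency == f], f)
  }))
  expect_equal(comp, tdb + cfg$source_level, tolerance = 1e-9)

  # symmetric directions of a symmetric beam receive equal levels
  sym_pose <- lingualsonar:::new_bat_pose(c(1.15, 1.15, 1.2), c(1, 0, 0),
                                          c(0, 0, 1))
  two_mics <- tibble::tibble(
    mic = 1:2, x = c(2.0, 2.0), y = c(1.45, 0.85), z = c(1.2, 1.2),
    fx = -1, fy = 0, fz = 0
  )
  obs2 <- synthesize_esd(truth, sym_pose, 0, two_mics, cfg)
  left_right <- dplyr::filter(obs2, frequency == 35e3)
  expect_equal(left_right$esd[1], left_right$esd[2], tolerance = 1e-9)
})

test_that("measurement noise has the configured spread", {
  cfg <- session_config(seed = 6, noise_sd = 1, frequencies = 35e3)
  mics <- make_mic_array()[1, ]
  tr <- make_trajectory(duration = 1)
  pose <- lingualsonar:::pose_at_time(tr$trajectory, 0.5)
  truth <- truth_gaussian()
  set.seed(123)
  reps <- vapply(1:400, function(i) {
    synthesize_esd(truth, pose, 0, mics, cfg)$esd
  }, numeric(1))
  expect_lt(abs(stats::sd(reps) - 1), 0.1)
})

test_that("identical session configurations give identical bundles", {
  cfg <- session_config(seed = 17, n_pairs = 4)
  b1 <- make_session(cfg)
  b2 <- make_session(cfg)
  expect_identical(b1$esd, b2$esd)
  expect_identical(b1$markers, b2$markers)
  expect_identical(b1$clicks, b2$clicks)
  # a different seed changes the data
  b3 <- make_session(session_config(seed = 18, n_pairs = 4))
  expect_false(identical(b1$esd, b3$esd))
})

test_that("bundles serialize to a readable CSV/YAML directory", {
  cfg <- session_config(seed = 2, n_pairs = 2)
  b <- make_session(cfg)
  tmp <- withr::local_tempdir()
  write_bundle(b, tmp)
  expect_true(all(file.exists(file.path(
    tmp, c("mics.csv", "trajectory.csv", "markers.csv", "clicks.csv",
           "esd.csv", "session.yaml")
  ))))
  esd_back <- utils::read.csv(file.path(tmp, "esd.csv"))
  expect_equal(nrow(esd_back), nrow(b$esd))
  meta <- yaml::read_yaml(file.path(tmp, "session.yaml"))
  expect_equal(meta$seed, 2)
})
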