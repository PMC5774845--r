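test_that("head pose from markers follows the marker construction", {
  p <- head_pose_from_markers(c(1, 0, 0), c(-1, 1, 0), c(-1, -1, 0))
  expect_equal(p$aim, c(1, 0, 0))
  expect_equal(p$normal, c(0, 0, 1))
  expect_equal(p$left, c(0, 1, 0))
  expect_equal(p$position, c(-1, 0, 0))

  # equivariance under a rigid rotation of the marker set
  R <- lingualsonar:::rotation_about(c(0, 1, 2) / sqrt(5), 0.9)
  rot <- function(v) drop(R %*% v)
  pr <- head_pose_from_markers(rot(c(1, 0, 0)), rot(c(-1, 1, 0)),
                               rot(c(-1, -1, 0)),
                               up = rot(c(0, 0, 1)))
  expect_equal(pr$aim, rot(p$aim), tolerance = 1e-12)
  expect_equal(pr$normal, rot(p$normal), tolerance = 1e-12)

  expect_error(
    head_pose_from_markers(c(2, 0, 0), c(0, 0, 0), c(1, 0, 0)),
    "collinear"
  )
})

test_that("trajectory fallback takes the horizontal tangent", {
  t <- seq(0, 2, by = 0.01)
  straight <- tibble::tibble(time = t, x = 1 + 2 * t, y = 0.5, z = 1.4)
  p <- head_pose_fallback(straight, 1)
  expect_equal(p$aim, c(1, 0, 0), tolerance = 1e-9)
  expect_equal(p$normal, c(0, 0, 1))
  expect_identical(p$source, "trajectory")

  climbing <- tibble::tibble(time = t, x = 1 + 2 * t, y = 0.5, z = 1 + t)
  pc <- head_pose_fallback(climbing, 1)
  expect_equal(pc$aim, c(1, 0, 0), tolerance = 1e-9)

  # circular level flight: aim tangent to the circle
  circ <- tibble::tibble(
    time = t, x = cos(pi * t), y = sin(pi * t), z = 1.2
  )
  pcirc <- head_pose_fallback(circ, 0.5)  # at angle pi/2: tangent (-1, 0)
  expect_lt(acos(sum(pcirc$aim * c(-1, 0, 0))) * 180 / pi, 1)

  stationary <- tibble::tibble(time = t, x = 1, y = 1, z = 1.4)
  expect_error(head_pose_fallback(stationary, 1), "stationary")
})

test_that("ESD compensation inverts the propagation model exactly", {
  med <- acoustic_medium()
  mic <- mic_spec(1, c(1, 0, 0))
  f <- seq(25e3, 55e3, by = 5e3)
  esd <- tibble::tibble(frequency = f, esd = c(80, 78, 75, 73, 70, 69, 67))

  # identity at the reference range with absorption off and a flat mic
  same <- compensate_esd(esd, mic, range = 0.1, med, absorption = FALSE)
  expect_equal(same$esd, esd$esd)

  # pure spreading: +20 log10(range / r_ref)
  spread <- compensate_esd(esd, mic, range = 2.0, med, absorption = FALSE)
  expect_equal(spread$esd - esd$esd, rep(20 * log10(20), length(f)),
               tolerance = 1e-9)

  # full round trip through the forward model
  raw <- lingualsonar:::apply_propagation(esd$esd, f, mic, 1.7, med)
  back <- compensate_esd(tibble::tibble(frequency = f, esd = raw), mic, 1.7,
                         med)
  expect_equal(back$esd, esd$esd, tolerance = 1e-9)

  expect_error(compensate_esd(tibble::tibble(frequency = 5e3, esd = 1),
                              mic, 1), "10-100 kHz")
  expect_error(compensate_esd(esd, mic, range = 0.05), "reference range")
})

test_that("microphone projection uses the bat-frame sign conventions", {
  pose <- head_pose_from_markers(c(1, 1, 1), c(0.9, 1.05, 1), c(0.9, 0.95, 1))
  # pose at (0.9, 1, 1) aiming +x, normal +z
  mics <- tibble::tibble(
    mic = 1:3,
    x = c(2.0, 0.9, 0.9),
    y = c(1.0, 2.0, 1.0),
    z = c(1.0, 1.0, 2.5)
  )
  proj <- project_mics_to_bat_frame(mics, pose)
  expect_equal(proj$azimuth[1], 0, tolerance = 1e-9)   # dead ahead
  expect_equal(proj$elevation[1], 0, tolerance = 1e-9)
  expect_equal(proj$azimuth[2], 90, tolerance = 1e-9)  # bat's exact left
  expect_equal(proj$elevation[2], 0, tolerance = 1e-9)
  expect_equal(proj$elevation[3], 90, tolerance = 1e-9)  # straight above
  expect_equal(proj$range[1], 1.1, tolerance = 1e-9)

  expect_error(
    project_mics_to_bat_frame(
      tibble::tibble(mic = 1, x = 0.9, y = 1, z = 1), pose
    ),
    "coincides"
  )
})

test_that("spherical RBF interpolation is exact and finds synthetic peaks", {
  dirs <- fibonacci_directions(34)

  # constant samples give a constant field (within the sampled support)
  const <- dplyr::mutate(dirs, db = -7)
  rc <- rbf_interpolate(const, fixture_grid5)
  expect_equal(rbf_predict(rc, c(0, 40, -60), c(10, -20, 5)), rep(0, 3),
               tolerance = 1e-6)

  # interpolation reproduces every sample to 1e-9 dB
  s <- gaussian_samples(dirs, center = c(10, -5))
  rb <- rbf_interpolate(s, fixture_grid2)
  pred <- rbf_predict(rb, s$azimuth, s$elevation)
  expect_equal(pred + rb$offset, s$db, tolerance = 1e-9)

  # the reconstructed main lobe peaks within 5 degrees of the true peak
  ctr <- beam_center(rb, rb$frequency[1])
  expect_lt(sqrt((ctr["azimuth"] - 10)^2 + (ctr["elevation"] + 5)^2), 5)

  dup <- dplyr::bind_rows(s, s[1, ])
  expect_error(rbf_interpolate(dup, fixture_grid5), "duplicate")
  expect_error(rbf_interpolate(s[1:3, ], fixture_grid5), "at least 5")
  narrow <- dplyr::mutate(s, azimuth = azimuth / 10)
  expect_error(rbf_interpolate(narrow, fixture_grid5), "span")
})

test_that("Eckert IV projection is exact, invertible and equal-area", {
  expect_equal(unlist(eckert4(0, 0)), c(x = 0, y = 0))

  az <- c(-170, -45, 0, 30, 120)
  el <- c(-80, -30, 10, 45, 70)
  p <- eckert4(az, el)
  back <- eckert4_inverse(p$x, p$y)
  expect_equal(back$azimuth, az, tolerance = 1e-6)
  expect_equal(back$elevation, el, tolerance = 1e-6)

  # area of a projected 1x1 degree cell matches the spherical cell area at
  # any latitude (equal-area property), to 1e-6 relative
  cell_area <- function(el0) {
    s <- seq(0, 1, length.out = 30)
    bx <- c(s, rep(1, 30), 1 - s, rep(0, 30))
    be <- c(rep(el0, 30), el0 + s, rep(el0 + 1, 30), el0 + 1 - s)
    q <- eckert4(bx, be)
    abs(sum(q$x * c(q$y[-1], q$y[1]) - c(q$x[-1], q$x[1]) * q$y) / 2)
  }
  sphere_area <- function(el0) {
    (sin((el0 + 1) * pi / 180) - sin(el0 * pi / 180)) * (pi / 180) *
      (180 / pi)^2
  }
  for (el0 in c(0, 40, 75)) {
    expect_equal(cell_area(el0) / sphere_area(el0), 1, tolerance = 1e-6)
  }
})

test_that("contour extraction selects the main lobe and flags degeneracies", {
  # circular Gaussian with a -3 dB radius of 20 degrees
  g <- direction_grid(1, 1)
  ae <- unit_to_sph(g$units)
  db <- -3 * ((ae$azimuth^2 + ae$elevation^2) / 20^2)
  beam <- lingualsonar:::new_beam_pattern(matrix(db, ncol = 1), g, 35e3)
  ct <- contour_minus3db(beam, 35e3)
  r <- sqrt(ct$azimuth^2 + ct$elevation^2)
  expect_true(all(abs(r - 20) < 1.5))
  expect_false(attr(ct, "boundary"))

  flat <- lingualsonar:::new_beam_pattern(
    matrix(rep(0, nrow(g$units)), ncol = 1), g, 35e3
  )
  expect_error(contour_minus3db(flat, 35e3), "entirely above")

  # two-lobed: the contour around the taller lobe is returned
  db2 <- pmax(
    -3 * (((ae$azimuth - 40)^2 + ae$elevation^2) / 15^2),
    -1 - 3 * (((ae$azimuth + 40)^2 + ae$elevation^2) / 15^2)
  )
  two <- lingualsonar:::new_beam_pattern(matrix(db2, ncol = 1), g, 35e3)
  ct2 <- contour_minus3db(two, 35e3)
  expect_true(all(ct2$azimuth > 0))
})

test_that("direct ellipse fitting recovers exact and noisy ellipses", {
  t <- seq(0, 2 * pi, length.out = 41)[-41]
  ctr <- eckert4(10, 5)
  scl <- lingualsonar:::eckert4_scales(10, 5)
  ax <- 12.5 * scl["sx"]
  by <- 18 * scl["sy"]
  pts <- tibble::tibble(x = ctr$x + ax * cos(t), y = ctr$y + by * sin(t))
  fit <- fit_ellipse(pts)
  expect_equal(unname(fit$center), c(10, 5), tolerance = 1e-6)
  expect_equal(fit$az_extent, 25, tolerance = 1e-6)
  expect_equal(fit$el_extent, 36, tolerance = 1e-6)
  expect_equal(fit$aspect_ratio, 36 / 25, tolerance = 1e-6)

  # circle: equal axes, rotation 0 by the tie-break
  circ <- tibble::tibble(x = 3 + 5 * cos(t), y = -2 + 5 * sin(t))
  fc <- fit_ellipse(circ)
  expect_equal(unname(fc$semi_axes[1]), unname(fc$semi_axes[2]),
               tolerance = 1e-9)
  expect_equal(fc$rotation, 0)

  # 1% radial noise: center recovered within 0.5 degrees
  set.seed(7)
  noisy <- tibble::tibble(
    x = ctr$x + ax * cos(t) * (1 + rnorm(length(t), 0, 0.01)),
    y = ctr$y + by * sin(t) * (1 + rnorm(length(t), 0, 0.01))
  )
  fn <- fit_ellipse(noisy)
  expect_lt(sqrt(sum((fn$center - c(10, 5))^2)), 0.5)

  expect_error(fit_ellipse(pts[1:4, ]), "at least 5")
  line <- tibble::tibble(x = 1:10, y = 2 * (1:10) + 3)
  expect_error(fit_ellipse(line), "ellipse")
})

test_that("beam center composes contouring and ellipse fitting", {
  g <- direction_grid(1, 1)
  ae <- unit_to_sph(g$units)
  db <- pmax(
    -3 * (((ae$azimuth - 15)^2 / 12.5^2 + (ae$elevation + 5)^2 / 18^2)),
    -60
  )
  beam <- lingualsonar:::new_beam_pattern(matrix(db, ncol = 1), g, 35e3)
  ctr <- beam_center(beam, 35e3)
  expect_lt(abs(ctr["azimuth"] - 15), 1)
  expect_lt(abs(ctr["elevation"] + 5), 1)

  # verification check: center close to the mean of the > -1 dB region
  npm <- near_peak_mean_direction(beam, 35e3)
  expect_lt(sqrt(sum((ctr - npm)^2)), 5)

  pist <- piston_beam(0.004, 35e3, grid = g)
  pc <- beam_center(pist, 35e3)
  expect_lt(max(abs(pc)), 1)
})

test_that("the five sampling-quality criteria behave as specified", {
  dirs <- tidyr::expand_grid(azimuth = seq(-80, 80, 20),
                             elevation = seq(-40, 40, 20))
  dense <- gaussian_samples(dirs, center = c(0, 0)) |>
    dplyr::mutate(db = db + 80)  # received levels well above the floor
  q <- quality_filter(dense)
  expect_true(q$pass)
  expect_equal(nrow(q$report), 5)

  # loudest microphone on the boundary of the sampled region
  edge <- dense
  edge$db[which.max(edge$azimuth)] <- max(edge$db) + 10
  qe <- quality_filter(edge)
  expect_false(qe$report$pass[qe$report$criterion == "max_mic_interior"])

  # too few neighbours with only 4 microphones
  q4 <- quality_filter(dense[c(1, 10, 20, 30), ] |>
                         dplyr::mutate(azimuth = c(-80, -30, 30, 80)))
  expect_false(q4$report$pass[q4$report$criterion == "neighbours_near_max"])

  # quiet click fails the signal-level criterion
  quiet <- dplyr::mutate(dense, db = db - 50)
  qq <- quality_filter(quiet)
  expect_false(qq$report$pass[qq$report$criterion == "snr"])

  expect_error(quality_filter(dense, criteria = list(az_span_min = 10)),
               "missing")
})
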