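# Alignment operates on per-microphone sample tables; fixtures are
# noiseless Gaussian beams sampled on a quasi-uniform 34-direction set.

dense_directions <- function() {
  # offset so no direction sits exactly on a 10-degree bin edge
  tidyr::expand_grid(azimuth = seq(-78, 87, 15),
                     elevation = seq(-48, 42, 15))
}

aligned_fixture <- function(center = c(0, 0)) {
  gaussian_samples(dense_directions(), center = center)
}

test_that("an already-centered click converges immediately with zero shift", {
  al <- align_click(aligned_fixture())
  expect_true(al$converged)
  expect_equal(al$iterations, 1)
  expect_lt(sqrt(sum(al$shift^2)), 0.6)
})

test_that("alignment recovers a known beam offset", {
  al <- align_click(aligned_fixture(center = c(10, -5)))
  expect_true(al$converged)
  expect_lt(abs(al$shift[1] + 10), 1)
  expect_lt(abs(al$shift[2] - 5), 1)
  # aligned samples now reconstruct to a centered beam
  rb <- rbf_interpolate(al$samples, direction_grid(2, 2))
  ctr <- beam_center(rb, rb$frequency[1])
  expect_lt(sqrt(sum(ctr^2)), 0.6)
})

test_that("alignment is translation-covariant", {
  base <- align_click(aligned_fixture(center = c(8, -4)))
  pre <- aligned_fixture(center = c(8, -4))
  pre$azimuth <- pre$azimuth + 6
  pre$elevation <- pre$elevation + 3
  shifted <- align_click(pre)
  expect_true(shifted$converged)
  expect_equal(unname(shifted$shift - base$shift), c(-6, -3),
               tolerance = 1)
})

test_that("merging identical aligned clicks reproduces the single click", {
  s <- aligned_fixture()
  avg <- merge_average(list(s, s, s), bin = 10, grid = direction_grid(1, 1),
                       frequency = 35e3)
  fit_avg <- fit_ellipse(contour_minus3db(avg, 35e3))
  single <- rbf_interpolate(s, direction_grid(1, 1), 35e3)
  fit_one <- fit_ellipse(contour_minus3db(single, 35e3))
  # the average equals the single click up to the 10-degree binning error
  expect_lt(sqrt(sum((fit_avg$center - fit_one$center)^2)), 7)
  expect_equal(fit_avg$aspect_ratio, fit_one$aspect_ratio, tolerance = 0.15)
  # occupied bins only; empty bins are absent, never zero-filled
  expect_true(all(avg$bins$n_clicks == 3))
  expect_lt(nrow(avg$bins), 36 * 18)
})

test_that("averaging commutes with a global left-right mirror", {
  set.seed(11)
  clicks <- lapply(1:6, function(i) {
    s <- gaussian_samples(dense_directions(),
                          center = c(runif(1, -3, 3), runif(1, -3, 3)))
    dplyr::mutate(s, db = db + rnorm(nrow(s), 0, 0.5))
  })
  mirrored <- lapply(clicks, function(s) dplyr::mutate(s, azimuth = -azimuth))
  g <- direction_grid(2, 2)
  a1 <- merge_average(clicks, grid = g, frequency = 35e3)
  a2 <- merge_average(mirrored, grid = g, frequency = 35e3)
  f1 <- fit_ellipse(contour_minus3db(a1, 35e3))
  f2 <- fit_ellipse(contour_minus3db(a2, 35e3))
  expect_equal(f1$center[1], -f2$center[1], tolerance = 0.5)
  expect_equal(f1$aspect_ratio, f2$aspect_ratio, tolerance = 0.02)

  expect_error(merge_average(list()), "no clicks")
})

test_that("beam metrics report widths, aspect ratios and frequency curves", {
  g <- direction_grid(1, 1)
  ae <- unit_to_sph(g$units)

  # circular beam: aspect ratio 1
  db_c <- pmax(-3 * (ae$azimuth^2 + ae$elevation^2) / 15^2, -60)
  bc <- lingualsonar:::new_beam_pattern(matrix(db_c, ncol = 1), g, 35e3)
  mc <- beam_metrics(bc)
  expect_equal(mc$aspect_ratio, 1, tolerance = 0.02)

  # 24 x 36 degree beam: aspect ratio 1.5
  db_e <- pmax(
    -3 * (ae$azimuth^2 / 12^2 + ae$elevation^2 / 18^2), -60
  )
  be <- lingualsonar:::new_beam_pattern(matrix(db_e, ncol = 1), g, 35e3)
  me <- beam_metrics(be)
  expect_equal(me$aspect_ratio, 1.5, tolerance = 0.075)
  expect_equal(me$az_extent, 24, tolerance = 1)
  expect_equal(me$el_extent, 36, tolerance = 1)

  # transmission-array model: the 25 kHz center is lateral (same sign as
  # the emitting side) relative to the 55 kHz center
  cfg <- default_array_config(mesh = fixture_head())
  b <- transmission_array_beam(cfg$array, cfg$tongue, c(25e3, 35e3, 55e3))
  m <- beam_metrics(b, reference_frequency = 35e3)
  offset25 <- m$center_azimuth[m$frequency == 25e3]
  expect_gt(offset25, 0)  # left-side array: positive azimuth = lateral
})
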