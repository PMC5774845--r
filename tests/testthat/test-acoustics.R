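test_that("acoustic medium checks consistency and derives sound speed", {
  med <- acoustic_medium()
  expect_equal(med$sound_speed, 343)
  derived <- acoustic_medium(sound_speed = NULL, temperature = 20)
  expect_equal(derived$sound_speed, 331.3 * sqrt(1 + 20 / 273.15))
  expect_error(acoustic_medium(sound_speed = 300, temperature = 20),
               "inconsistent")
  expect_equal(wavenumber(35e3), 2 * pi * 35e3 / 343)
})

test_that("atmospheric absorption has the expected magnitude and trends", {
  a35 <- atmospheric_absorption(35e3)
  # around 1 dB/m for ultrasound at room conditions, rising with frequency
  expect_gt(a35, 0.3)
  expect_lt(a35, 3)
  f <- c(25e3, 35e3, 45e3, 55e3)
  expect_true(all(diff(atmospheric_absorption(f)) > 0))
})

test_that("piston directivity matches its closed form", {
  grid <- direction_grid(0.5, 2)
  med <- acoustic_medium()
  # ka = 5 at radius a: f = 5 * c / (2 pi a)
  a <- 0.004
  f5 <- 5 * med$sound_speed / (2 * pi * a)
  b <- piston_beam(a, f5, med, grid)
  expect_equal(max(b$db), 0)
  # on-axis (0, 0) is the global maximum
  i0 <- which(abs(b$grid$units[, 1] - 1) < 1e-12)
  expect_equal(b$db[i0, 1], 0)

  # axisymmetry: same off-axis angle, same level (az vs el cut)
  el0 <- which.min(abs(grid$elevation - 0))
  m <- beam_slice(b, f5)
  cut_az <- m[, el0]
  az0 <- which.min(abs(grid$azimuth - 0))
  expect_equal(m[az0 + 40, el0], m[az0 - 40, el0], tolerance = 1e-9)

  # first null at asin(3.8317/5) ~ 50.0 degrees, within one grid cell
  theta_null <- asin(3.8317 / 5) * 180 / pi
  right <- cut_az[grid$azimuth >= 0 & grid$azimuth <= 90]
  az_right <- grid$azimuth[grid$azimuth >= 0 & grid$azimuth <= 90]
  expect_lt(abs(az_right[which.min(right)] - theta_null), 0.5 + 1e-9)
})

test_that("piston beams narrow with frequency and stay on axis", {
  freqs <- seq(25e3, 55e3, by = 10e3)
  b <- piston_beam(0.004, freqs, grid = direction_grid(1, 1))
  met <- beam_metrics(b)
  expect_true(all(diff(met$az_extent) < 0))
  expect_true(all(abs(met$center_azimuth) < 1))
  expect_true(all(abs(met$center_elevation) < 1))
})

test_that("the array factor obeys the classical steering law", {
  med <- acoustic_medium()
  f <- 35e3
  k <- wavenumber(f, med)
  lambda_mm <- 1000 * med$sound_speed / f
  d_mm <- lambda_mm / 2
  n <- 8
  pos <- cbind(0, (seq_len(n) - (n + 1) / 2) * d_mm, 0)
  grid <- direction_grid(0.25, 5, az_range = c(-89, 89))
  el0 <- which.min(abs(grid$elevation - 0))
  n_az <- length(grid$azimuth)
  for (dphi in c(-1.2, -0.6, 0, 0.6, 1.2)) {
    p <- array_factor(pos, (seq_len(n) - 1) * dphi, f, med, grid)
    cut <- Mod(p)[(el0 - 1) * n_az + seq_len(n_az)]
    az_peak <- grid$azimuth[which.max(cut)]
    # exp(i(phi_n - k x_n.u)) peaks where k d sin(az) = dphi
    theta_s <- asin(dphi / (k * d_mm / 1000)) * 180 / pi
    expect_lt(abs(az_peak - theta_s), 0.25 + 1e-9)
  }
})

test_that("free-field array limiting cases match closed forms", {
  med <- acoustic_medium()
  f <- 35e3
  lambda_mm <- 1000 * med$sound_speed / f
  grid <- direction_grid(1, 5)

  # single element: omnidirectional
  arr1 <- lingualsonar:::new_array_spec(matrix(c(0, 0, 0), 1), "left",
                                        "discrete")
  b1 <- freefield_array_beam(arr1, tongue_position(c(-5, 0, 0)), f,
                             med, grid)
  expect_equal(max(b1$db) - min(b1$db), 0, tolerance = 1e-9)

  # two elements, lambda/2 spacing, equal ranges: |cos((pi/2) sin az)|^2
  arr2 <- lingualsonar:::new_array_spec(
    rbind(c(0, lambda_mm / 4, 0), c(0, -lambda_mm / 4, 0)),
    "both", "discrete"
  )
  b2 <- freefield_array_beam(arr2, tongue_position(c(-10, 0, 0)), f,
                             med, grid)
  el0 <- which.min(abs(grid$elevation - 0))
  m2 <- beam_slice(b2, f)
  az <- grid$azimuth
  expected <- 10 * log10(pmax(cos(pi / 2 * sin(az * pi / 180))^2, 1e-12))
  keep <- expected > -40
  expect_equal(m2[keep, el0], expected[keep], tolerance = 1e-6)

  # equal ranges: mirror symmetry about the broadside plane
  expect_equal(m2[match(30, az), el0], m2[match(-30, az), el0],
               tolerance = 1e-9)
})

test_that("coherent combination obeys the phase-shift identities", {
  grid <- direction_grid(5, 5)
  f <- 35e3
  set.seed(42)
  vals <- complex(
    real = stats::rnorm(nrow(grid$units)),
    imaginary = stats::rnorm(nrow(grid$units))
  )
  field <- structure(list(values = vals, grid = grid, frequency = f),
                     class = "element_field")

  # single field: combination is that field's normalized pattern,
  # whatever the range (a global phase)
  one <- combine_elements(list(field), 7.7)
  direct <- 20 * log10(Mod(vals))
  expect_equal(one$db[, 1], direct - max(direct), tolerance = 1e-9)

  # adding a constant to every range leaves the pattern unchanged
  f2 <- structure(list(values = vals * (0.3 + 1i), grid = grid,
                       frequency = f), class = "element_field")
  base <- combine_elements(list(field, f2), c(3, 5))
  shifted <- combine_elements(list(field, f2), c(3, 5) + 12.34)
  expect_equal(base$db, shifted$db, tolerance = 1e-9)

  # two identical fields half a wavelength apart in range cancel deeply
  lambda_mm <- 1000 * acoustic_medium()$sound_speed / f
  inphase <- combine_elements(list(field, field), c(10, 10))
  anti <- combine_elements(list(field, field), c(10, 10 + lambda_mm / 2))
  ipk <- which.max(inphase$db[, 1])
  raw_in <- 20 * log10(Mod(2 * vals[ipk]))
  raw_anti <- 20 * log10(Mod(vals[ipk] *
                               (1 + exp(1i * wavenumber(f) * lambda_mm / 2000))))
  expect_gte(raw_in - raw_anti, 40)

  # mismatched grids are refused
  bad <- structure(list(values = vals[1:10], grid = direction_grid(30, 30),
                        frequency = f), class = "element_field")
  expect_error(combine_elements(list(field, bad), c(1, 2)), "share grid")
})

test_that("every beam pattern is normalized to 0 dB at each frequency", {
  cfg <- default_array_config(mesh = fixture_head())
  b <- transmission_array_beam(cfg$array, cfg$tongue, c(25e3, 40e3, 55e3),
                               grid = fixture_grid2)
  expect_equal(unname(apply(b$db, 2, max)), c(0, 0, 0))
  expect_true(all(b$db <= 0))
  p <- piston_beam(0.004, c(30e3, 50e3), grid = fixture_grid5)
  expect_equal(unname(apply(p$db, 2, max)), c(0, 0))
})

test_that("beam patterns round-trip through long-format CSV", {
  b <- piston_beam(0.004, c(30e3, 50e3), grid = direction_grid(10, 10))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_beam_csv(b, tmp)
  b2 <- read_beam_csv(tmp)
  expect_equal(b2$db, b$db, tolerance = 1e-9)
  expect_equal(b2$frequency, b$frequency)
  expect_equal(b2$grid$azimuth, b$grid$azimuth)
})
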