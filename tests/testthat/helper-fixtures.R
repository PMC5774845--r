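# Shared fixtures, built once per test run. Coarse meshes and grids keep
# the unit tests fast; the acceptance tests use the documented defaults.

fixture_head <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_simplified_head(edge_target = 1)
    cache
  }
})

fixture_grid5 <- direction_grid(5, 5)
fixture_grid2 <- direction_grid(2, 2)

# a well-spread set of sample directions (spherical Fibonacci points),
# mimicking a 34-channel array's angular coverage
fibonacci_directions <- function(n = 34, cap_elevation = 65) {
  i <- seq_len(n) - 0.5
  phi <- (1 + sqrt(5)) / 2
  el <- asin(1 - 2 * i / n) * 180 / pi * (cap_elevation / 90)
  az <- ((360 * i / phi) %% 360) - 180
  tibble::tibble(azimuth = az, elevation = el)
}

# synthetic anisotropic Gaussian beam samples with known center and widths
gaussian_samples <- function(dirs, center = c(0, 0), az_width = 25,
                             el_width = 36, floor = -60) {
  dplyr::mutate(
    dirs,
    db = pmax(
      -3 * ((azimuth - center[1]) / (az_width / 2))^2 -
        3 * ((elevation - center[2]) / (el_width / 2))^2,
      floor
    )
  )
}

deg2rad_test <- function(x) x * pi / 180
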