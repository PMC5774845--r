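Package: lingualsonar
Title: Tongue-Driven Sonar Beam Steering Models and Beam-Pattern Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward models and reconstruction tools for the biosonar beam of
    lingual-echolocating fruit bats (Rousettus aegyptiacus). Implements the
    transmission-array beam formation model, in which elements along the
    narrow mouth opening radiate with phase shifts set by their distances to
    the clicking tongue and are summed coherently, alongside the classical
    circular-piston comparator and an exterior Helmholtz boundary-element
    solver for radiation around the head. Provides the microphone-array
    beam-pattern reconstruction pipeline (energy-spectral-density
    compensation, bat-frame projection, radial basis function interpolation
    on the sphere, Eckert IV equal-area contouring, direct ellipse fitting,
    click quality criteria), iterative beam-axis alignment with binned
    averaging, a synthetic flight-room experiment generator, and scripted
    experiments including tongue-steering sweeps, sensitivity suites, Monte
    Carlo sampling validation and rank-sum comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
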