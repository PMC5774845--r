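# lingualsonar

Egyptian fruit bats (*Rousettus aegyptiacus*) echolocate with tongue
clicks and can redirect their sonar beam by tens of degrees between two
clicks emitted ~20 ms apart, without any visible movement of the head or
mouth. `lingualsonar` implements the physics that explains this — a
**transmission-array model** in which elements along the narrow mouth
opening re-radiate the tongue click with phase shifts set by their
distances to the tongue — together with the full measurement pipeline
used to reconstruct sonar beam patterns from a microphone array around a
free-flying bat, and a synthetic flight-room experiment generator so that
every stage runs and is tested without any recordings.

The core model: with wavenumber `k = ω/c` and tongue-to-element ranges
`r_n`, the far field is the coherent sum

    P_total(u) = Σₙ Pₙ(u) · exp(i k rₙ)

where `Pₙ` is the field of the n-th aperture element — either the
exterior-Helmholtz solution for a monopole on the rigid head (built-in
boundary-element solver, validated against the analytic rigid-sphere
series) or a fast analytic baffled element. Because the phase profile
scales with `k` and is reshaped wholesale by moving a single point (the
tongue), the model produces the two hallmarks observed in the bat:
tongue-position beam steering, and a main lobe that sits lateral at low
frequencies and swings toward the midline at high frequencies. A
circular-piston comparator, the conventional model of mouth-emitting
biosonar, shows neither.

The measurement pipeline mirrors the experimental analysis: energy
spectral densities are compensated for spreading, ISO 9613-1 atmospheric
absorption and microphone response; projected into a bat-centred
azimuth–elevation frame from marker-derived head poses (with a
trajectory-tangent fallback); interpolated with an exact thin-plate
spline in great-circle distance; contoured at −3 dB under the Eckert IV
equal-area projection; and summarized by a direct least-squares ellipse
whose center defines the beam center. Clicks pass five spatial-sampling
quality criteria, are iteratively aligned so their 35 kHz beam axis sits
at the origin, and are averaged in 10° bins.

## Worked example

```r
library(lingualsonar)

cfg  <- default_array_config()       # simplified head, 8 left-side elements
beam <- transmission_array_beam(cfg$array, cfg$tongue)  # 25-55 kHz, fast mode
beam_metrics(beam)[, 1:3]
#>   frequency center_azimuth center_elevation
#> 1     25000           42.0            -16.3
#> 2     30000           41.2            -16.9
#> 3     35000           40.3            -17.2
#> 4     40000           39.2            -17.5
#> 5     45000           38.1            -17.7
#> 6     50000           36.9            -17.8
#> 7     55000           35.5            -18.0
```

The left-side aperture throws the beam to the bat's left (positive
azimuth), and the center azimuth falls monotonically from 42.0° at 25 kHz
to 35.5° at 55 kHz — the frequency-dependent sweep toward the midline.
The 35 kHz `aspect_ratio` column gives 1.59: the main lobe is elongated
in elevation, like the measured clicks. Moving only the tongue steers
the beam:

```r
sw <- steering_sweep(cfg$array, seq(0, 6, length.out = 5),
                     base_tongue = cfg$tongue,
                     direction = cfg$steer_direction)
attr(sw, "extent"); attr(sw, "monotone")
#> [1] 46.77208
#> [1] TRUE
autoplot(sw)
```

A 6 mm tongue displacement swings the 35 kHz beam center monotonically
through 46.8°; with the element block shifted toward the rostrum the same
displacement yields 55.4°. And the full synthetic pipeline recovers what
it is fed:

```r
truth  <- truth_gaussian(az_width = 25, el_width = 36)
bundle <- make_session(session_config(seed = 1, n_pairs = 100, truth = truth))
recon  <- reconstruct_session(bundle)
fit <- fit_ellipse(contour_minus3db(pooled_average(recon, 35e3), 35e3))
fit$center; fit$aspect_ratio
#>    azimuth  elevation
#> -0.5132104 -0.1580958
#> [1] 1.526525
```

From 200 noisy clicks (1 dB measurement noise, 34 microphones) the
averaged beam lands within ~0.5° of the true center and within 7% of the
true aspect ratio (1.43 measured through the same contour machinery).

## Package layout

- geometry: `build_simplified_head()`, `place_elements()`,
  `tongue_position()`, `element_ranges()`, `read_mesh()`/`write_mesh()`
- forward models: `piston_beam()`, `freefield_array_beam()`,
  `bem_element_field()`, `combine_elements()`,
  `transmission_array_beam()`
- reconstruction: `head_pose_from_markers()`, `compensate_esd()`,
  `rbf_interpolate()`, `eckert4()`, `contour_minus3db()`,
  `fit_ellipse()`, `beam_center()`, `quality_filter()`
- alignment/averaging: `align_click()`, `merge_average()`,
  `beam_metrics()`, `reconstruct_session()`, `pooled_average()`
- synthetic experiments: `session_config()`, `make_session()`,
  `truth_gaussian()`/`truth_piston()`/`truth_array()`
- experiments/statistics: `steering_sweep()`, `sensitivity_suite()`,
  `monte_carlo_validation()`, `model_comparison()`, `rank_sum_test()`

Result objects are tibble-friendly: `tidy()`, `glance()` and
`autoplot()` methods are provided throughout. The methods vignette
(`vignettes/transmission-array-model.Rmd`) documents the model, the
numerical choices and the generator's assumptions in detail.
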