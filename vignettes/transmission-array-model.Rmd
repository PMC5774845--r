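---
title: "The transmission-array model and beam-pattern reconstruction pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The transmission-array model and beam-pattern reconstruction pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lingualsonar)
```

Egyptian fruit bats (*Rousettus aegyptiacus*) echolocate with tongue
clicks rather than laryngeal calls, emitting left- then right-pointing
clicks about 20 ms apart whose beam axes can differ by up to 60 degrees —
with no visible movement of the head or mouth. This package implements the
physical model that explains the steering, and the measurement pipeline
that reconstructs sonar beam patterns from a microphone array around a
flying bat.

## The transmission-array model

The narrow mouth opening is treated as an array of `N` transmitter
elements along the lip line, each re-radiating the click produced by the
tongue inside the mouth. An element at range `r_n` from the tongue
radiates with the phase of the path already travelled, so the far field is
the coherent sum

```
P_total(u) = sum_{n=1..N} P_n(u) * exp(i * k * r_n),        k = omega / c
```

where `P_n` is the field radiated by element `n` alone and the
tongue-to-element phase factors carry no amplitude weighting. Unlike an
engineered phased array, the phases are not set per element: moving one
point (the tongue) reshapes the whole phase profile at once, and because
the phases scale with the wavenumber `k`, the beam direction is
frequency-dependent. These are exactly the two signatures observed in the
bat: the beam is steered by tongue position, and within one click the main
lobe sweeps from lateral (low frequency) toward the midline (high
frequency).

Two realizations of `P_n` are provided:

* **BEM mode** — `bem_element_field()` solves the exterior Helmholtz
  problem for a unit monopole just outside the rigid head surface (direct
  collocation, piecewise-constant flat triangles, `G = exp(ikR)/(4 pi R)`
  with the `exp(-i w t)` convention). Interior (CHIEF) collocation points
  guard the irregular interior resonances; the overdetermined system is
  solved by least squares. We chose CHIEF over Burton–Miller coupling
  because it requires no hypersingular operator on constant elements and
  is fully adequate at the `ka` values of a 4 cm head below 55 kHz. The
  solver is validated against the analytic spherical-harmonic series for a
  monopole near a rigid sphere: at `ka = 1–2` with edges below an eighth
  of a wavelength the relative far-field RMS error is below 1% and
  decreases under refinement.
* **Fast mode** — `freefield_array_beam()` replaces the per-element BEM
  solve with an analytic element. A purely isotropic (monopole) element is
  available and is the textbook free-field array: it reproduces the
  classical steering law `sin(theta_s) = dphi / (k d)` and the two-element
  interference pattern exactly. For the head-mounted aperture, however,
  isotropic elements are a poor stand-in for the BEM fields: the
  phased arc then has a degenerate coherence cone, rear lobes dominate,
  and the frequency-dependent center shift runs *away* from the midline.
  The default fast-mode element is therefore a Kirchhoff-style baffled
  source with obliquity factor `(1 + cos g)/2` about the element's
  outward surface normal — the simplest analytic approximation to "a
  monopole radiating off a rigid head". With it, the model shows all the
  measured signatures at desk cost (about a second for a seven-frequency
  beam map).

The piston comparator (`piston_beam()`) is the conventional model of
mouth-emitting biosonar: `D = 2 J1(ka sin t)/(ka sin t)` in an infinite
baffle, radiating into the front half space. Its beam is circular, its
multi-frequency structure concentric, and its center never leaves the
axis — the features the bat's clicks do *not* show.

### Canonical geometry and configuration

Rather than depending on a scanned head, the canonical geometry is the
simplified artificial head: a
latitude–longitude ellipsoid tapered toward the rostrum with
compact-support ear bumps, scaled so its bounding box is exactly
40 x 25 x 25 mm (`build_simplified_head()`, millimetres; acoustics
converts to metres internally). The mouth line is the rostral arc of the
lip-seam row, tagged left/right of the sagittal plane. Conventions: x is
the head aim (rostral), z dorsal, y = z × x (bat's left); azimuth is
positive to the bat's left, elevation positive dorsal.

Where exactly the aperture elements sit along the mouth, and where the
tongue clicks, are not precisely known for the animal, so the default
configuration (`default_array_config()`) was chosen once:
8 discrete elements spread over the caudal three quarters of the left lip
seam, tongue at (10, 2, -3) mm. It reproduces, in fast mode, an
elevation-elongated 35 kHz main lobe (aspect ratio about 1.6), a monotone
center shift toward the midline over 25–55 kHz, a tongue-steering sweep of
tens of degrees over a 6 mm displacement along (1, -1, 0)/sqrt(2), and a
strictly larger sweep when the element block sits more rostrally
(`arc_range = c(0, 0.75)`) — closer to the tongue, so the phase profile
changes faster per millimetre of tongue travel. A "continuous" aperture
is a dense discrete array (spacing well below a tenth of the 55 kHz
wavelength).

```{r signature, eval = FALSE}
cfg <- default_array_config()
beam <- transmission_array_beam(cfg$array, cfg$tongue)
beam_metrics(beam)
autoplot(beam, frequencies = c(25e3, 35e3, 55e3))
```

## Beam-pattern reconstruction

A click's beam pattern is reconstructed from per-microphone energy
spectral densities (ESDs):

1. **Pose.** The head frame comes from three head markers (aim from the
   rear-marker midpoint to the front marker; normal from their cross
   product). If a marker is missing, the aim falls back to the horizontal
   tangent of the smoothed flight trajectory with a vertical normal.
2. **Compensation.** Each ESD is corrected by spherical spreading
   `20 log10(range / 0.1 m)`, atmospheric absorption (the ISO 9613-1
   analytic model, our choice of absorption formula), microphone
   sensitivity and directivity (flat by default).
3. **Projection and interpolation.** Microphone directions are projected
   into the bat frame and the compensated levels interpolated with an
   exact thin-plate spline in great-circle distance
   (`rbf_interpolate()`); the kernel choice is ours — only the method
   family is standard for this reconstruction.
4. **Contour and ellipse.** The -3 dB contour of the normalized pattern is
   extracted under the Eckert IV equal-area projection and summarized by a
   direct least-squares ellipse fit; the ellipse center *is* the beam
   center, and angular extents are reported with the projection's local
   scale compensated (the map stretches elevation by about 1.4 at the
   origin).
5. **Quality screening.** Five parameterized criteria
   (`quality_criteria()`): azimuth span >= 120 deg, elevation span >=
   60 deg, the loudest microphone interior to the sampled region's convex
   hull, at least 5 microphones within 30 deg of it, and peak level at
   least 10 dB above the noise floor. The thresholds are declared
   approximations, all exposed in configuration.

### Numerical safeguards

Thin-plate interpolation is exact at the samples but is pure extrapolation
inside angular coverage holes, where it can diverge spectacularly (we
observed spikes hundreds of dB above the beam peak, 60 degrees from the
nearest microphone). Three safeguards keep the downstream geometry tied to
the measurements, at the cost of saying nothing about unsampled
directions:

* the gridded field is floored wherever no sample lies within 25 degrees;
* it is clamped above at the beam's local peak estimate — the
  interpolant's maximum within 15 degrees of the loudest sample. Clamping
  at the loudest *sample* instead would bias the normalization low
  (the true peak usually falls between microphones) and widen every
  -3 dB ellipse by 10–30%;
* contour selection for measured beams is anchored at the loudest
  measurement rather than the grid maximum.

## Alignment and averaging

Individual clicks point in many directions, so before averaging, each
click's microphone coordinates are iteratively shifted until the center of
its best-fitting 35 kHz ellipse lands on the origin (tolerance 0.5 deg,
at most 20 iterations). Two departures from the plain iteration proved
necessary: steps are damped (factor 0.7) because marginally sampled
clicks otherwise oscillate between two fixed points, and the final
sub-tolerance center is applied too, because the leftover residual is
correlated with the approach direction and biased the population average.
The alignment could in principle rotate the projected coordinates as well
as shift them; a rotation that stabilizes the ellipse's major-axis angle
is implemented behind `rotate = TRUE`, with pure shifting as the default.
Clicks that do not converge, or whose aligned lobe is clipped by the grid
edge or degenerate, are excluded.

Aligned clicks are merged in 10-degree azimuth–elevation bins (per-bin
means of per-click-normalized levels; empty bins stay missing and are
never zero-filled) and the bin means are interpolated with the same
spherical spline, separately for left- and right-pointing clicks. For
synthetic sessions, where right-pointing clicks are exact mirror images of
one underlying model, `pooled_average()` additionally mirrors the
right-side clicks onto the left and merges everything into a single
estimate — twice the clicks, and the natural estimator when there is one
truth to recover.

## The synthetic experiment generator

`make_session()` emulates the flight-room experiment so the whole pipeline
runs with no external data: a 2.3 x 2.3 x 2.4 m room; 34 microphones —
dense 4 x 4 grids on the two walls the flight corridor points toward
(spanning 18–92% of the room height, so elevation coverage is symmetric
about the flight height) plus two on the corner edge between them; a
straight, level flight segment through the covered quadrant carrying the
three head markers (each dropping out independently, 5% by default);
click pairs 20 ms apart at 10 pairs/s, sides alternating left/right, with
the pair's inter-click angle drawn uniformly from 20–60 degrees and split
evenly about the head aim; and per-microphone ESDs sampled from a truth
beam model with source level, spreading, absorption and i.i.d. Gaussian
noise in dB (1 dB default) applied so that `compensate_esd()` inverts the
propagation part exactly. Everything is reproducible from the session
seed.

Design notes on the generator, decided once and kept: the microphone
placement concentrates directional sampling where the beams point, as the
real array did — with microphones spread uniformly over all four walls,
the five quality criteria (the neighbour criterion especially) reject
about 90% of clicks, which no measurement campaign would accept; the
trajectory is the measurable segment of a trial rather than a full
wandering flight; and the analytic Gaussian truth beam has a -60 dB
sidelobe floor, because real ESDs bottom out at the noise floor rather
than falling by hundreds of dB behind the animal.

What the generator deliberately does not emulate: waveform-level acoustics
(no time series, no reverberation of the foam-lined room), microphone
hardware quirks (sensitivity curves default flat), head roll, or click
spectral variation between clicks. Tests passing on these synthetic
sessions therefore validate the pipeline's geometry, compensation,
interpolation, alignment and averaging — not its robustness to waveform
segmentation or calibration errors in real recordings.

## Validation experiments

* `steering_sweep()` — beam-center azimuth at 35 kHz for a series of
  tongue positions; reports extent and monotonicity.
* `sensitivity_suite()` — discrete vs continuous one-sided apertures,
  forward-shifted block, ears removed, and the two-sided symmetric
  aperture with a midline tongue. One-sided variants keep the elongated
  shape and the monotone frequency shift; the two-sided case is
  mirror-symmetric with its center pinned to the midline, so it cannot
  produce the one-sided signatures. (In fast mode the ear variant only
  acts through element positions and normals; capturing ear scattering
  itself requires BEM mode.)
* `monte_carlo_validation()` — full sessions from known truth models
  through reconstruction, alignment and averaging; at the standard
  conditions (34 microphones, 200 clicks, 1 dB noise) the pooled estimate
  recovers the truth's 35 kHz beam center to well under a degree and its
  aspect ratio within 10%, and with zero noise the residual error is the
  10-degree binning alone. Per-side estimates have roughly 0.85 deg
  standard error in each center coordinate — the pooled estimator exists
  because halving that variance matters at these sample sizes.
* `model_comparison()` + `rank_sum_test()` — per-click ellipse-feature
  distributions for a "data-like" arm (array truth, higher noise), the
  array model arm and the piston arm, compared pairwise with a
  Mann–Whitney test (exact enumeration up to a combined n of 12, ties
  included; normal approximation with tie correction above). The aspect
  ratio cleanly separates the elongated array beams from round piston
  beams.

## Problem sizes and defaults

Reconstruction and model evaluation use a 1-degree grid; alignment
iterations use a 2-degree grid (ellipse centers are sub-grid accurate, so
this costs no precision at a quarter of the evaluation cost). BEM
validation uses spheres of 320–1280 elements; multi-frequency beam maps
use 25–55 kHz in 5 kHz steps, covering the clicks' usable band at a
resolution fine enough to show the center sweep. The medium
defaults to 20 °C, 50% RH, 101.325 kPa, c = 343 m/s. Reference range for
spreading compensation: 0.1 m.

## Known limitations

* The simplified head is a re-creation from a verbal description, not a
  replica; absolute beam directions and widths depend on the element and
  tongue placements, which are approximations. Qualitative signatures
  (elongation, shift direction, steering monotonicity) are the supported
  claims.
* Fast mode's baffled element is an uncontrolled approximation to the BEM
  per-element field; it is flagged in beam metadata and BEM mode remains
  the reference.
* The reconstruction says nothing outside the microphone support; beams
  aimed at coverage holes are screened out rather than recovered.
* Serialization uses CSV/JSON/YAML (and STL/OBJ for meshes) throughout.
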