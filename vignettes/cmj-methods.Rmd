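---
title: "Methods: countermovement-jump temporal analysis and method agreement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: countermovement-jump temporal analysis and method agreement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmjkit)
```

## Scope and model

`cmjkit` analyses one countermovement jump (CMJ) per trial from planar
(sagittal X–Z) trajectories of 14 body landmarks, and provides the
statistics battery used to quantify agreement between two measurement
methods (typically marker-based motion capture and markerless pose
estimation). The pipeline is deliberately rule-based and deterministic:
given the same input and configuration it always produces the same events
and variables.

### Centre of mass

The whole-body CoM uses a four-segment Dempster model. Segment mass
fractions are foot 0.015, lower leg 0.0465, upper leg 0.10, upper body
0.43; they sum to 0.5915 and the weighted mean is renormalised by that sum
rather than the weights being rescaled to one — the remaining body mass
(arms, head) is assumed to move with the measured segments. Segment CoM
locations: foot at the heel–big-toe midpoint, lower leg at 43.3% of the
ankle→knee length from the ankle, upper leg at 43.3% of the knee→hip length
from the knee, upper body at the hip–shoulder midpoint. The directions are
read literally: the along-segment fraction originates at the distal
reference marker of each pair. The foot midpoint uses the big toe (not the
small toe) because the big toe is also the marker whose height defines the
flight phase. The same formula is applied to X and Z; the model is
equivariant under rigid translation, and the CoM is a convex combination of
the segment CoMs (both properties are tested).

### Event grammar

Nine events are detected on three series — CoM height, CoM vertical
velocity (central differences, one-sided at the edges) and big-toe
height — and must satisfy `a < c < d < e <= f < g < h <= i`:

* **f, h** (lift-off, touchdown): the toe trace is thresholded at
  `toe_baseline + max(min_height_m, 5·noise_sd)`; the longest excursion is
  the flight; `f`/`h` are the first/last airborne samples after backtracking
  to the contact level `toe_baseline + noise_sd`. Baselines and `noise_sd`
  come from the initial quiet-stance window.
* **d**: argmin of CoM height before `f`; **c**: argmin of velocity up to
  `d`; **e**: argmax of velocity on `(d, f]`; **g**: argmax of height
  strictly between `f` and `h`; **i**: argmin of height from `h` on. All
  ties break toward the earlier index.
* **a** (onset): searching backward from `c`, the first sample whose
  downward speed exceeds `onset_fraction` (default 0.05) of the reference
  velocity. The reference is the maximum upward velocity
  (`onset_reference = "max_up"`, the literal reading of "5% of the maximum
  velocity"); `"max_down"` (5% of peak downward speed) is available because
  the phrasing is genuinely ambiguous in the field. The backward search
  makes the onset robust to pre-trial fidgeting.

An ordering violation raises an error naming the offending pair; more than
one flight excursion raises an ambiguous-trial error (one jump per trial is
assumed); a flat or monotone CoM trace fails with a detection error.

### Variables

Phase durations are index differences over the sampling rate. Displacements
are relative to the quiet-stance CoM baseline. Max and min vertical
velocity are taken over the ground-contact push-off interval `[a, f]`, not
the whole trial, so landing transients cannot dominate; the printed minima
of roughly −2.2 m/s in validation studies correspond to the countermovement
descent, which is consistent with this choice. Push-off joint angles are
sampled at `d`, landing angles at `i`. Angles are **interior** angles at the
joint (180° = fully extended), computed from the arc-cosine of the clipped
normalised dot product; mapping to anatomical conventions (e.g. ankle
dorsiflexion relative to the shank) is left to the user and documented
here because published magnitudes are compatible with several conventions.

Two numerical refinements avoid 1-sample discretisation where it matters:

* **Flight time** is not `(h − f)/fs`. The toe crossings of the lift-off
  threshold are located by linear interpolation (the crossing is
  transversal there, unlike at the baseline where the toe rests), and the
  chord is converted by the exact ballistic relation
  `t_flight = sqrt(dt_chord² + 8L/g)` with `L` the threshold height above
  the toe baseline. At 100 Hz an integer-index flight time carries up to
  2 samples (~0.02 s) of error, i.e. up to ~0.02 m in the `g·t²/8` height.
* **Take-off velocity** is the velocity series linearly interpolated at the
  refined take-off instant (velocity is linear in time through lift-off
  under free flight); the raw sample at `f` overestimates by up to
  `g/fs`.

With these, the three jump-height estimators (CoM displacement, `g·t²/8`,
`v²/2g`) agree within 0.01 m on noise-free simulated jumps — tested across
the full parameter sweep.

`g` defaults to 9.81 m/s² and is configurable.

### Smoothing

`cmj_analyze()` applies a centred moving average (default window 0.05 s,
set 0 to disable) to the CoM height and again to the differentiated
velocity; windows are truncated at the series edges, so constants are
preserved and the output never extends the input range. The toe trace is
left **unsmoothed**: its flight excursion is two orders of magnitude above
landmark noise, and smoothing correlates the noise, which biases the
threshold backtracking at lift-off and touchdown. A zero-phase exponential
moving average (`ema_filter()`, forward–backward averaged, default
`alpha = 0.3`) is provided for markerless exports; the zero-phase form is a
deliberate choice so that smoothing cannot shift event timing, even though
single-pass (phase-lagging) EMA is common in streaming pipelines.
Gap filling is linear or local-polynomial (default cubic over five present
samples per side), refuses leading/trailing gaps, and defaults to a maximum
fillable gap of 0.1 s — occlusions are brief; longer gaps indicate tracking
failure and should fail loudly.

## Agreement statistics

For paired per-trial values (or pooled curve stations) of a reference
method `x` and comparison method `y`, with `d = y − x`:

* **Bland–Altman**: bias = mean(d); LoA = bias ± 1.96·sd(d) (sample SD);
  bias CI via `t(0.975, n−1)·sd/√n`; LoA CIs via the approximation
  `SE = sd·√(3/n)`.
* **RMSE** = `sqrt(mean(d²))`; note the identity
  `rmse² = bias² + (n−1)/n·sd(d)²` (tested).
* **Pearson r** with Fisher-z CI (`SE = 1/√(n−3)`) and the conventional
  magnitude labels (negligible < 0.3 … very high ≥ 0.9).
* **ICC(3,1)**: two-way mixed, consistency, single measures,
  `(BMS − EMS)/(BMS + (k−1)·EMS)` from the targets × raters mean squares,
  CI from the F-distribution bounds on `BMS/EMS`. The consistency form is
  insensitive to additive offsets between methods but **not** to
  rescalings — a common misreading; the tests pin both behaviours.
* **Two-way fully-within ANOVA** (method × side, trial as the blocking
  case): each within factor and the interaction is tested against its own
  case-by-factor interaction error term, so with `n` cases the error df is
  `n − 1` per effect. Published CMJ validation tables sometimes print
  error df that cannot be reconstructed from any standard within-within
  scheme at their stated design size; this package reports its own df and
  does not attempt to match such values.
* **Cohen's d, harmonic-SD form**: `d = (m₂ − m₁)/hsd`,
  `hsd = 2·s₁·s₂/(s₁+s₂)`; CI via the normal approximation
  `SE = √((n₁+n₂)/(n₁n₂) + d²/(2(n₁+n₂)))`; magnitude labels trivial < 0.2
  … very large > 1.3; the effect is *unclear* iff the CI spans both −0.20
  and +0.20. `cohens_d_from_summary()` computes the same statistic from
  printed means/SDs so published tables can be re-derived. Both trial-level
  and subject-mean aggregation are exposed in `compare_methods()` because
  validation reports rarely state which was used.
* **Curve-level agreement**: trials are time-normalised to 101 stations
  (0–100%), per-station means get t-based 95% CI bands, and the pooled
  bias/LoA/RMSE/r are computed over all stations of all trials
  concatenated. Pooling over stations is this package's convention for
  whole-curve statistics; per-station pooling weights every phase of the
  movement equally regardless of trial duration.

## The synthetic generator

`simulate_cmj()` builds the CoM height profile as C¹ (continuous position
and velocity) piecewise segments with fully known event times:

* quiet stance (1.0 s default), then a cosine-eased unweighting
  (0.24 s) to the commanded peak downward velocity at **c** and a braking
  segment (0.18 s) to the bottom at **d**, with total descent equal to
  `depth_m` (0.30 m default);
* the bottom is crossed with acceleration ≈ 1 g, continuous from the
  braking to the propulsive side (capped so the braking velocity stays
  monotone). This mirrors the ground-reaction-force peak at the squat
  bottom; an eased profile with zero acceleration there would have a
  quartic-flat, physically implausible minimum that no detector could
  localise under noise;
* propulsion: a time-warped cosine rise to the take-off velocity
  (`takeoff_velocity_mps`, 2.3 m/s default; the warp exponent is solved so
  the propulsive displacement equals the depth — the take-off posture
  equals the stance posture), then a symmetric quadratic velocity peak of
  half-width `B = min(0.03 s, 0.2·depth/v)` whose descending branch reaches
  slope −g exactly at lift-off. The velocity maximum (**e**) therefore
  precedes take-off by `B` and exceeds the take-off velocity by `g·B/2`
  (≤ 0.15 m/s), matching the observed max ≥ take-off ordering, and the CoM
  follows a single flight parabola from **e** to touchdown;
* exact ballistic flight of duration `2v/g` (so flight time, apex height
  and take-off velocity are mutually consistent closed forms — the
  strongest available self-consistency oracle), a cosine-eased landing to
  `landing_depth_m` (0.25 m) at **i**, and a half-sine recovery.

The defaults reproduce the magnitudes reported for adult jumpers in
marker-based testing (unweighting ≈ 0.24 s, braking ≈ 0.18 s, depth
≈ 0.29–0.31 m, take-off velocity ≈ 2.3 m/s, flight ≈ 0.47 s). The ground
truth for event **a** is the analytic crossing of the onset threshold, so
the commanded `unweighting_s` (movement start to **c**) is slightly longer
than the measurable unweighting phase (onset to **c**); detected variables
are compared against the ground-truth struct, and braking/propulsive
durations equal their commanded values exactly.

Landmarks are back-generated from the target CoM by inverting a hinged
planar posture model (fixed flat foot; shank, thigh and trunk rotate with a
single crouch parameter; segment lengths scaled to `stature_m`) per sample
with a bisection tolerance of 1e-13, so the Dempster CoM of the landmark
set reproduces the target within ~1e-12 m; during flight the take-off
posture translates rigidly. Measurement error is applied last: per-landmark
vertical Gaussian noise plus a constant bias, seeded. Applying noise to
landmarks rather than to the CoM exercises the noise-averaging of the
Dempster weighting. `degrade()` applies the same error model to an existing
set (z only), emulating the systematic and random discrepancy between two
capture methods.

What the generator does **not** emulate: arm swing (hands-on-hips technique
is assumed), mediolateral motion, soft-tissue artefact, autocorrelated or
heteroscedastic pose-estimation error, heel raise during push-off (the toe
and heel stay at their baselines until lift-off), multi-jump trials, and
asymmetry between sides (both sides are generated identically). Passing
tests therefore demonstrate correctness of the *algorithms* under a clean,
controlled signal model — not field accuracy of any capture system.

## Numerical choices and degenerate inputs

* Ties in extremum searches break toward the earlier index everywhere.
* Central differences are used for velocity (second-order, unbiased);
  edges use one-sided differences, exact for linear signals.
* The arc-cosine argument in joint angles is clipped to [−1, 1];
  zero-length rays are an error naming the sample.
* `moving_average()` truncates the window at the edges rather than padding,
  so constants are fixed points and no spurious trend is introduced.
* Gap filling never modifies present samples; unfillable gaps report their
  span.
* `bland_altman()` requires n ≥ 3, `pearson_r()` n ≥ 4 and non-degenerate
  variance, `icc_3_1()` a complete table, the ANOVA a fully crossed
  balanced design; all fail with explicit messages otherwise.
* All simulation randomness flows through explicit integer seeds; the RNG
  state is restored afterwards.

## Problem sizes

The test-suite and acceptance runs use 100 Hz trials of ~3 s (~300
samples); the event-recovery sweep covers 50 parameter combinations
(depths 0.15–0.45 m × take-off velocities 1.8–2.8 m/s, with
`propulsive_s = max(0.22, 1.5·depth/v)` so the take-off-at-baseline
geometry stays feasible across the grid), each analysed noise-free and with
2 mm landmark noise; bias-recovery pools 60 trials × 101 stations. These
sizes keep the full suite under a minute on one core while leaving the
Monte-Carlo margins wide.

## Known limitations

* 2D sagittal analysis only; no 3D marker sets, no kinetics (forces,
  power, impulse), no anthropometric scaling beyond the fixed Dempster
  fractions.
* One jump per trial; drop jumps and repeated hops are out of scope.
* The interior-angle convention may differ from anatomical reporting
  conventions by a complement; users comparing against published angle
  tables should verify the convention first.
* The harmonic-SD Cohen's d CI is a normal approximation; for very small
  samples it is optimistic.
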