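---
title: "kinemark: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{kinemark: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinemark)
```

This vignette explains what `kinemark` computes and why the pipeline is
built the way it is: the joint-angle model, the preprocessing decisions, the
agreement statistics, the synthetic-data generator that serves as the test
oracle, and the limitations of each.

## The measurement problem

A mobile device films a patient performing a rehabilitation exercise; a pose
estimator emits, per video frame, a set of named body landmarks in
normalized image coordinates (fractions of frame width/height, origin
top-left, y increasing *downward*) with a visibility confidence in [0, 1].
The clinical question is whether joint angles derived from those landmarks
can stand in for goniometry — the clinician's handheld protractor — for hip
and knee flexion in post-arthroplasty follow-up. `kinemark` implements both
halves: the signal pipeline that turns landmarks into range-of-motion (ROM)
values, and the method-comparison statistics that quantify agreement with
the clinical reference.

## Joint angles

All three angles are planar (sagittal-view) angles between segment vectors,
computed with the dot-product formula
\[
\theta = \arccos\!\Big(\mathrm{clamp}\Big(\tfrac{u\cdot v}{\lVert u\rVert\,\lVert v\rVert},\,-1,\,1\Big)\Big)\cdot\tfrac{180}{\pi}\in[0,180].
\]
The clamp matters: for nearly collinear vectors, floating-point rounding can
push the normalized dot product infinitesimally outside [−1, 1], where
`acos` returns `NaN`. Clamping turns that into an exact 0° or 180°.

* **Hip**: thigh vector (Hip→Knee) against the fixed vertical axis (0, −1).
* **Knee**: thigh (Hip→Knee) against shank (Knee→Ankle); 0° = straight leg.
* **Ankle**: shank (Knee→Ankle) against foot (Ankle→Toe).

**Hip conventions.** In y-down image coordinates, the axis (0, −1) points
*up-image*, so the raw arccos value is 180° for an upright (down-pointing)
thigh. Clinically, hip flexion is the deviation *from* upright posture.
Both readings are exposed: `raw_eq1` (the verbatim arccos output, the
default) and `flexion` (180° − raw, 0° when standing). Neither is asserted
to be "the" right one — the ambiguity is inherent to referencing a y-down
frame against a vertical axis, and the choice is a display convention, not
a modelling one. Knee and ankle angles are unaffected because both of their
vectors rotate with the body.

**Aspect correction.** Angles computed directly on normalized coordinates
are distorted whenever the frame is not square (a 16:9 frame compresses x
by 16/9). When the source frame size is known, coordinates are mapped to
(x·width, y·height) before vectors are formed; when it is not, the package
warns and proceeds on the raw coordinates. The synthetic generator always
records its frame size (1920×1080), so its angles are exact.

**Degenerate frames.** Coincident landmarks (zero-length segment vector)
indicate tracking failure. Such frames raise an error in the single-frame
functions and are skipped with a warning — never silently emitted as 0° — in
the series pipeline.

## Preprocessing

The pipeline order is: fill landmark gaps → compute per-frame angles →
resample to a uniform grid → low-pass filter.

**Gap filling.** A landmark is *missing* in a frame when it is absent or its
visibility falls below a threshold (default 0.5, the conventional midpoint;
the estimator's confidence scale is not calibrated, so this is a parameter,
not a constant). Interior gaps are filled per coordinate by straight-line
interpolation in timestamp between the bracketing valid frames —
proportional distribution along the connecting line. Leading/trailing gaps,
which have no bracket, hold the nearest valid value. Filled samples are
flagged, and every angle sample that used a filled landmark carries
`origin = "interpolated"`, so downstream consumers can weigh provenance.
The operation is idempotent and filled values never leave the bracketing
interval.

**Resampling.** Mobile capture runs at a variable 15–20 Hz, while a digital
filter with a fixed cutoff needs a fixed sampling rate. Angle series are
therefore linearly resampled onto a uniform grid. The default rate is the
median observed frame interval's reciprocal — using the observed rate
rather than a fixed 20 Hz minimizes interpolation distortion, since most
grid points then fall near actual samples.

**Butterworth smoothing.** A 4th-order Butterworth low-pass at 6 Hz — the
biomechanics convention for kinematic signals, passing voluntary human
movement (≤ ~6 Hz) while attenuating landmark jitter. Two modes:

* `zero_phase` (default, offline analysis): the filter is run forward and
  backward, cancelling phase lag so peak *timing* is preserved; the
  magnitude response is squared, so the gain at the cutoff is 0.5 rather
  than the single-pass 1/√2. Edge transients are controlled by
  odd-reflection padding of length 3·(order+1) with steady-state initial
  conditions. Because the padding depends on the signal's ends, plain
  forward–backward filtering is not exactly symmetric under time reversal;
  `kinemark` therefore averages the forward–backward and
  backward–forward runs, which makes the operator exactly time-reversal
  symmetric while leaving the steady-state response unchanged.
* `causal`: a single forward pass, as a streaming (real-time overlay)
  deployment would apply; it preserves fidelity to what an app computes
  live, at the cost of phase lag.

Filtering is applied to the *angle* series, not to landmark coordinates:
the angle is the measurand, and filtering it directly makes the smoothing
spectrally interpretable. DC gain is exactly 1 in both modes (a constant
angle is never shifted).

```{r filter-gains}
fs <- 60
t <- seq(0, 10, by = 1 / fs)
x <- sin(2 * pi * 6 * t)
amp <- function(y, keep = t > 3 & t < 7) {
  s <- sin(2 * pi * 6 * t)[keep]; cc <- cos(2 * pi * 6 * t)[keep]
  sqrt(sum(coef(lm(y[keep] ~ s + cc - 1))^2))
}
c(causal = amp(butterworth_lowpass(x, filter_spec(4, 6, fs, "causal"))),
  zero_phase = amp(butterworth_lowpass(x, filter_spec(4, 6, fs))))
```

## Repetitions and range of motion

The clinical protocol repeats each exercise three times and analyses the
mean. `kinemark` segments repetitions as local maxima of the filtered angle
series with *topographic prominence* of at least 10° and peak-to-peak
separation of at least 1 s; boundaries sit at the minima between retained
peaks. Prominence (rather than a fixed height threshold) makes segmentation
invariant to baseline offsets and robust to sub-threshold wiggles; the
defaults separate physiological repetitions from jitter at 15–20 Hz but are
exposed as parameters, since exercise cadence varies. `rom_deg` is the
arithmetic mean of the repetition peaks and can never exceed the global
peak flexion.

## Agreement statistics

**ICC(A,1).** The single-measure, absolute-agreement intraclass correlation
under a two-way model (subjects × raters, k = 2 raters: clinical and
algorithm), computed from the two-way ANOVA mean squares:
\[
\mathrm{ICC}(A,1)=\frac{MS_R-MS_E}{MS_R+(k-1)MS_E+\tfrac{k}{n}(MS_C-MS_E)}.
\]
Absolute agreement is the clinically meaningful form here: a method that
tracks patients perfectly but reads 10° high should *not* score 1, and the
MS_C term makes sure it does not (the consistency form, kept internally as
a comparison oracle, ignores it). The 95% CI uses the F-based procedure
with Satterthwaite degrees of freedom; the p-value tests ICC = 0 via
F = MS_R/MS_E on (n−1, (n−1)(k−1)) df. These are the standard formulas for
the (A,1) notation; the implementation computes mean squares directly from
row/column means, and the test suite verifies it against an independent
`aov()`-based computation and a frozen reference from an independent ICC
implementation.

**Bland–Altman.** Differences are oriented **algorithm − clinical**
throughout — negative bias means the algorithm under-reads. This is stated
prominently because sign conventions are a recurring source of confusion in
method-comparison reporting. Limits of agreement are bias ± 1.96·sd with
the n−1 sd denominator; no CI on the LoA is reported by default. The
proportional-bias check regresses differences on pair means (a non-zero
slope means accuracy depends on the magnitude of flexion).

**Error vs covariate.** Signed or absolute error regressed on a covariate
(e.g., months since surgery) by OLS, with Spearman's rank correlation as
the distribution-free companion. Spearman p-values use the t-approximation
on midranks; an exact permutation option exists for n ≤ 7, where full
enumeration (≤ 5040 permutations) is cheap — beyond that the approximation
is adequate and enumeration is not.

**Cohort summaries** report per-column mean (2 dp), min and max, and
patient counts by procedure; a bilateral hip replacement counts as one THA
patient.

## The synthetic generator

`simulate_motion()` poses a sagittal-plane chain — hip fixed, thigh, shank
and foot segments of normalized lengths 0.22/0.20/0.07 (plausible on-screen
proportions for full-body capture at ~2.5 m) — driven by a raised-cosine
flexion profile reaching `peak_deg` once per repetition. The raised cosine
is C¹-smooth with negligible energy above 1 Hz at exercise cadence, so the
6 Hz filter passes it essentially unchanged and filter effects can be
isolated in tests. The geometry is constructed in the aspect-corrected
plane of a 1920×1080 frame and projected to normalized y-down coordinates,
so angles recomputed from the landmarks equal the driving profile
analytically (verified to 1e-6° in the tests) — the generator is an
end-to-end oracle, not just a fixture factory.

Degradations mirror what a pose estimator produces: i.i.d. Gaussian
coordinate noise (default study condition 0.003 normalized units),
Bernoulli visibility dropout per frame and landmark (5%), and frame-interval
jitter (±10% around the nominal 18 Hz, inside the observed 15–20 Hz band).
All randomness flows from a single seed; the same spec and seed reproduce
bit-identical sequences.

What the simulator does **not** emulate: structured pose-estimator error
(temporally correlated drift, left/right swaps, occlusion-correlated bias),
perspective and lens distortion, soft-tissue artefact, or out-of-plane
motion. Passing tests therefore demonstrate correctness of the *pipeline*
under known conditions, not clinical validity of any particular pose
estimator — the latter requires paired recordings against goniometry.

`simulate_two_way_table()` draws paired measurements from
value = μ + subject + rater offset + noise, whose population ICC(A,1) is
subject_sd² / (subject_sd² + offset²/2 + error_sd²); it backs the estimator
recovery, CI coverage, and test-size simulations.

## Numerical choices and degenerate inputs

* Dot products clamped to [−1, 1]; vectors shorter than 1e-9 raise rather
  than return 0°.
* Angle JSON and landmark JSON round-trip to better than 1e-9 (full-precision
  serialization, fixed key order).
* The zero-phase filter needs series longer than the padding (> 15 samples
  at order 4); shorter series raise an explicit error.
* Interpolation requires ≥ 2 valid frames per landmark; fewer raises an
  "unusable landmark" error naming the landmark.
* An ICC on a zero-variance table is undefined and raises; a perfect-match
  table returns exactly 1 with a degenerate CI.
* Ties in Spearman use midranks; two-level covariates still regress.

## Problem sizes used in validation

The simulation-based checks run at deliberately modest sizes chosen to make
the Monte Carlo error small relative to the tolerance checked: 500
replicates for ICC recovery and CI coverage at the study size n = 14, 1000
replicates for the proportional-bias test size, 10 000 pairs for
Bland–Altman moment recovery, and 20 simulated recordings (~215 frames
each) for end-to-end ROM recovery. The cohort summary uses the packaged
14-row pilot table.

## Known limitations

* 2D only: angles are projections; out-of-sagittal-plane motion biases
  them. No pelvis-referenced hip flexion, frontal/transverse angles, or
  gait events.
* The hip angle references the image vertical, not gravity: camera tilt
  translates directly into hip-angle offset (knee/ankle are immune).
* Gap filling is linear; long occlusions produce straight-line motion where
  the true limb path curved. Kalman or spline filling is out of scope.
* The repetition segmenter assumes discrete flexion-extension cycles; it is
  not an exercise classifier and will under-segment continuous oscillation
  faster than the separation parameter.
* Agreement statistics assume one value per subject per method (the
  averaged-repetitions protocol); repeated-measures Bland–Altman and
  mixed-model agreement are out of scope.
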