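---
title: "Methods: head-speed and gaze compliance scoring for VORx1 exercises"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: head-speed and gaze compliance scoring for VORx1 exercises}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vorx)
```

## 1. The problem

Gaze-stabilization (VORx1) exercises ask a patient to oscillate the head in
one plane (yaw for horizontal, pitch for vertical movements) at a
metronome-prescribed tempo while keeping the eyes on a fixed target. A
camera-based monitoring system observes a head-angle time series
$\theta(t)$ — degrees versus seconds, sampled non-uniformly at roughly the
camera frame rate — and must answer two questions objectively: *was the head
moving at the prescribed speed*, and *was the gaze on target*. This package
implements that scoring, the head-pose estimator that produces $\theta(t)$
from facial landmarks, and the harness used to validate a camera pipeline
against an IMU reference.

## 2. Beat–cycle convention

All tempo arithmetic relies on one convention, fixed package-wide: **one
metronome beat is one sweep to one extreme**, so a full oscillation
(peak-to-peak) spans two beats and the ideal same-kind interval at goal
tempo $g$ bpm is $120/g$ seconds. This reading is forced by the
frequency-error identity (Section 6), whose ideal interval is $120/g$, and
it makes `interval_bpm(dt) = 120/dt` for peak-to-peak intervals and
`60/dt` for adjacent peak–valley intervals.

## 3. Head-speed compliance pipeline

### 3.1 Smoothing

Frame intervals from a tablet camera vary by a few milliseconds, which rules
out naïve Fourier methods and fixed-width sample filters. `smooth_series()`
is a *time-aware* centred moving average: every sample is replaced by the
mean of all samples within $\pm w/2$ seconds ($w$ = 0.15 s by default,
about five samples at 30 fps). Endpoints use truncated windows; $w = 0$ is
the identity. The default of 0.15 s is short relative to the fastest
supported half-cycle (0.375 s at 160 bpm), attenuating that sinusoid by
only ~6% while suppressing frame-level estimation noise.

### 3.2 Baseline

"Zero" is never observed directly: camera-derived head angles carry a DC
component (neutral pose is not exactly zero yaw). The baseline is defined
as the **whole-signal mean**, subtracted before extrema detection; heights
in reports are relative to this baseline.

### 3.3 Peak retention rule

On the centred signal, the list of local maxima is filtered by two rules:

1. **Prominence rule** — a maximum is retained iff its topographic
   prominence (height above the highest saddle separating it from any
   higher point) is at least its height above baseline. This is equivalent
   to keeping only the single largest maximum inside each positive region
   bounded by a baseline crossing on each side: a lesser lobe in the same
   region is separated from the bigger one by a saddle above baseline, so
   its prominence falls short of its height.
2. **Height threshold** — extrema shorter than 4° are dropped, so small
   perturbations are not counted as head turns.

Valleys are obtained by running the identical procedure on the negated
signal.

**Endpoint convention.** The bounded-region rule leaves regions touching
the signal ends ambiguous. The package treats the signal endpoints as
returns to baseline — formally, prominence is computed on the centred
signal zero-padded at both ends. Without this, a signal beginning exactly
at baseline (e.g. a sinusoid starting at phase 0) would keep or lose its
first extremum depending on the floating-point sign of the subtracted
mean. The test-suite oracle implements the *prominence* route on the same
padded signal by brute force; the production path implements the
*region-maximum* route; their exact agreement on hundreds of random
signals is what establishes the equivalence claimed above.

**Alternation.** After merging peaks and valleys, two same-kind extrema can
be adjacent (thresholding can delete an intervening extremum). The rule:
within a same-kind run, keep the largest absolute height; ties keep the
earlier. The output therefore strictly alternates.

### 3.4 Classification and scoring

Each consecutive same-kind pair yields `measured_bpm = 120/dt`, labelled
`correct` iff $|measured - g| \le \Delta$ (default $\Delta = 15$ bpm),
otherwise `slow`/`fast`. **Percent-correct is interval-count weighted**,
not duration weighted — the simplest reading of "percentage of the exercise
conducted correctly", and the one stated in every report. A trial with
fewer than two same-kind extrema produces a flagged report with `NA`
percent rather than an error.

Gaze compliance is simply the percentage of frames labelled on-target.
Rewards: 5 coins for completing the exercise, plus `round(5·p/100)` coins
for each of head-speed and gaze percent `p`, rounding half away from zero
(the scale end-points 0 and 5 are pinned; the rounding direction at
half-integers is a free choice, fixed and documented here). Coins are
integers in $[0, 15]$ and monotone in each percentage.

## 4. Synthetic trial generator

The generator emulates what the analysis assumes about real trials:

* **Latent motion** — a phase-modulated sinusoid
  $\theta(t) = dc + A\,\sin\phi(t)$ with
  $\dot\phi = 2\pi\,\mathrm{bpm}(t)/120$. No specific motion model is
  prescribed by the underlying study; a sinusoid matches the waveform of
  recorded head-yaw traces.
* **Tempo drift** — $\mathrm{bpm}(t)$ is a Gaussian random walk (step s.d.
  `speed_drift_sd_bpm`·$\sqrt{dt}$, default 2 bpm) reflected at
  goal ± 3 s.d., so a "compliant but human" subject wanders a few bpm
  without sign flips. Drift also breaks the exact periodicity that would
  make cross-correlation lag estimation ambiguous (Section 5).
* **Frame jitter** — sample times are the nominal camera grid (default
  30 fps) plus independent Gaussian offsets (default s.d. 4 ms), sorted
  and de-tied: "the time difference between two consecutive frames is not
  constant".
* **Amplitude decay** — effective amplitude is
  $A - 0.05\,(g - 80)$ deg (clamped at 0), anchored at 80 bpm: subjects
  measurably reduce range of motion at faster tempi. Default $A$ = 15°,
  matching the prescribed ±15° sweep.
* **Noise** — additive Gaussian angle noise (default s.d. 1°).
* **Paired trials** — camera and IMU sample the same latent phase path.
  The camera keeps DC, gains extra noise (default 0.5° on top), and is
  delayed by `lag_s`; the IMU samples a uniform 100 Hz grid and has its
  empirical mean removed exactly (IMU-derived angles carry no DC
  component). The injected lag/DC truth is returned for assertions.

Neither the camera nor the IMU sampling rate is stated in the source
study; 30 fps (typical tablet camera) and 100 Hz (typical IMU) are
conventions, chosen once. All generators are bit-reproducible under a
fixed seed, implemented by saving and restoring the caller's RNG state.

**What a green test does *not* establish.** The generator produces
stationary sinusoid-like motion with Gaussian noise. Real camera-derived
angles have heavy-tailed, pose-dependent error (landmark occlusion grows
with head eccentricity), dropped frames, and non-stationary subjects
(fatigue, corrections after metronome slips). Green acceptance tests
establish that the *metric definitions and algorithms* behave correctly on
signals with the assumed structure — not that a particular tablet achieves
any particular accuracy on patients.

## 5. Camera-vs-IMU validation harness

`align_series()` interpolates both series onto a uniform grid at the
median camera interval over the overlapping span (≥ 5 s required),
mean-removes both, and scans integer grid shifts within ±`max_lag_s`
(default 2 s) for the maximum normalized cross-correlation; the DC
compensation added to the aligned reference is
`mean(camera) − mean(reference)` (identical to the camera mean when the
reference is zero-mean, which the IMU contract guarantees, but robust
otherwise). The aligned reference is then resampled at the camera
timestamps, so angle errors are evaluated on the camera clock.

Lag resolution is one grid interval (~1/30 s); no sub-sample interpolation
of the correlation peak is attempted, since the acceptance requirement is
exactly "within one resample interval". For strictly periodic signals the
correlation has equal maxima one period apart; the simulator's tempo drift
(and any real subject's) breaks the tie. The search bound of ±2 s follows
the observation that camera/IMU lags are a consistent, sub-second affair;
callers with pathological setups can widen it.

`match_peaks()` pairs same-kind extrema greedily by nearest time within a
tolerance of half a beat (30/g s) — unmatched extrema ("a head turn one
system missed") are counted and excluded, and `interpeak_errors()`
compares consecutive matched same-kind intervals between the systems.

**Per-trial frequency error.** The head-turn frequency of a trial is
defined as 120 / (mean same-kind interval); the reported
`mean_abs_head_turn_frequency_error_bpm` is its absolute deviation from
the *prescribed goal*, and the RMSE is over per-interval bpm values versus
the goal. Alternatives (camera-vs-IMU frequency difference, per-interval
mean) are defensible; this estimator is the package's fixed, documented
choice, and the frequency-error identity of Section 6 is exposed
separately for interval-error propagation analysis.

`classification_metrics()` computes accuracy, precision, recall and F1
from a confusion matrix with on-target as the positive class. Zero
denominators yield `NA` plus an explicit `undefined` marker — never a
silent zero.

## 6. Frequency-error identity

With ideal interval $120/g$ and interval error $\varepsilon$,

$$\mathrm{err}_{bpm} \;=\; g\left(\frac{-\varepsilon}{120/g + \varepsilon}\right)
\;=\; \frac{120}{120/g + \varepsilon} - g .$$

Both forms are implemented and tested to $10^{-9}$ over $10^4$ random
pairs; for fixed $\varepsilon > 0$, $|\mathrm{err}_{bpm}|$ is strictly
increasing in $g$ — the reason percent-correct agreement between camera
and IMU degrades at faster tempi even when interval errors do not.

## 7. Head pose from landmarks

### 7.1 Conventions

Intrinsic yaw–pitch–roll, applied in that order:
$R = R_y(\mathrm{yaw})\,R_x(\mathrm{pitch})\,R_z(\mathrm{roll})$, degrees,
with $x$ to the subject's left, $y$ up, $z$ toward the camera; positive
yaw turns the head to the subject's left, positive pitch looks up. The
source study never states its convention; the geodesic metric and the
round-trip tests are convention-independent, and per-axis errors are
meaningful only relative to this documented choice.

### 7.2 Solver

Under scaled-orthographic (weak-perspective) projection — appropriate
because no camera intrinsics are available — the centred image points obey
$P \approx s\,\Pi R X$ with $\Pi$ the 2×3 truncation. The solver computes
the least-squares 2×3 map $A = P^\top X (X^\top X)^{-1}$, takes its SVD
$A = U\Sigma V^\top$, sets the rotation's top two rows to $UV^\top$ (the
nearest scaled-row-orthonormal matrix), the scale to the mean singular
value, and the third row to the cross product of the first two
(determinant +1 by construction). Degenerate inputs are rejected: fewer
than 4 named correspondences, centred model rank < 3, or a rank-deficient
2×3 fit (pose ambiguous). For noise-free projections the top rows are
recovered exactly, hence the 1e-6° round-trip guarantee across the tested
grid (yaw ±60°, pitch ±45°, roll ±30°).

The built-in `canonical_face_model()` is a six-landmark rigid model
(eye corners, nose tip, mouth corners) with the nose tip off-plane; it is
an implementation constant standing in for whatever landmark detector
feeds the pipeline, not an anthropometric standard.

### 7.3 Error metrics

`rotation_errors()` reports per-axis mean $|\Delta|$, the MSE pooled over
all three angles and all frames, and the mean quaternion geodesic
$2\arccos(|q_1\cdot q_2|)$. The geodesic is a metric on the tested
domain; note $\textit{geodesic} \ge \max$ per-axis error is *false* in
general and deliberately not asserted — the property tested instead is
geodesic $= 0 \iff$ all per-axis errors $= 0$.

## 8. Numerical choices and degenerate inputs

* Strictly increasing timestamps are enforced at construction; the
  simulator de-ties jittered times with a nanosecond ladder.
* `acos` arguments are clamped to $[-1, 1]$; quaternions are normalized
  and sign-fixed to $w \ge 0$ before comparison.
* Interval classification uses closed windows ($\le \Delta$ is correct),
  so a measurement exactly on the boundary is compliant.
* The height threshold is applied to smoothed, baseline-relative heights
  (the raw-versus-smoothed question is unanswered upstream; smoothed is
  what the detector actually sees).
* Empty extrema lists, gaze series and sessions fail loudly or produce
  flagged reports; nothing silently coerces to zero.
* CSV round-trips print 17 significant digits, so `write` → `read` is
  bit-lossless for doubles.

## 9. Known limitations

* Batch analysis only; the near-real-time behaviour of a deployed app is
  a deployment concern outside the library.
* The pose solver ignores perspective: at short target distances the
  weak-perspective assumption biases large yaws/pitches. Occlusion-driven
  landmark loss — the dominant real-world failure — is not modelled.
* Percent-correct weighting (count vs duration) changes scores on trials
  with highly variable intervals; both systems in a paired comparison use
  the same definition, so comparisons remain fair.
* The lag search assumes a single global lag; drifting clocks are not
  modelled.
* Printed per-trial accuracy tables from the original validation study
  depend on unreleased recordings and are deliberately not reproduction
  targets; the harness reproduces the metric *definitions* and the
  qualitative bounds on synthetic data.
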