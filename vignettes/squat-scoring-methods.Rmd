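---
title: "Methods: pose-based squat scoring and audio feedback"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pose-based squat scoring and audio feedback}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(squatscore)
```

## The problem and the model

A camera-facing exerciser performs a fixed-cadence set of body-weight
squats: 10 repetitions, each 6 s (3 s descending, 3 s ascending), 60 s in
all, paced by a counting voice. A pose-estimation network reduces each
video frame to 17 named keypoints with 2-D image coordinates (y increases
downward) and a confidence. `squatscore` turns those trajectories into a
per-repetition quality score on three indices and a per-round audio volume
envelope. The package assumes the frontal view throughout: widths are
horizontal (x-axis) keypoint separations, which for a camera-facing
subject are robust to the slight forward crouch of a squat, and no
sagittal (side-view) measures are attempted.

Three signals drive the rubric:

* the **stance ratio** `Width_Knee / Width_Shoulder × 100%`,
* the **normalized hip height** `Height_Hip(t) / Height_Hip(0) × 100%`,
* the **rhythm** — the hip trajectory min-max rescaled to `[-1, 1]`
  within each round and compared with `Optimal(t) = cos(πt/3)`.

`Height_Hip` is the elevation of the hip midpoint **above the knee
midpoint** (left/right averaged), not height above ground. This choice is
forced by the depth rubric itself: the full-depth band is
`min ≤ 0`, with worked values around −10%, and only a knee-referenced
elevation crosses zero exactly when the hip reaches parallel. Partial,
parallel and full squat depths then map onto progressively lower minima of
the normalized signal.

## From keypoints to signals

`derive_series()` applies, in order:

1. **Confidence masking.** A sample of a signal is undefined when any
   contributing keypoint has confidence below `min_confidence`
   (default 0.2, the usual floor for treating pose-network output as a
   detection).
2. **Interpolation and resampling.** Defined samples are linearly
   interpolated onto a uniform grid at the sequence's nominal frame rate.
   Undefined gaps up to `max_gap = 0.5` s are bridged; longer gaps abort
   with an unusable-segment error rather than inventing half a repetition
   of motion. Interpolation happens directly onto the uniform grid — on
   the near-uniform input grids involved this is equivalent to
   interpolating first and resampling after, and it guarantees an NA-free
   uniform output.
3. **Smoothing.** A centered moving average of `smoothing_window = 0.2` s
   (edge windows shrink symmetrically). 0.2 s attenuates frame-to-frame
   pose jitter while leaving a 6-s period cosine essentially intact
   (attenuation < 1%).

The **baseline** `Height_Hip(0)` is the median hip elevation over the
first 0.5 s of the recording rather than literally the first frame; a
single noisy first frame would otherwise rescale the whole set. The
baseline must be positive — a hip at or below the knees while "standing"
is reported as a degenerate posture, not scored.

Both scored signals are ratios of pixel distances, so scores are invariant
under scaling and translation of the image coordinates; the test suite
asserts this property on jittered simulations.

## Segmentation

Rounds are cut by the clock, not by movement: `segment_fixed()` produces
`n_rounds` contiguous half-open windows `[t0 + 6(k−1), t0 + 6k)`. A sample
falling exactly on a boundary belongs to the later window, which keeps the
partition exact (every sample in exactly one window). Fixed-cadence
segmentation mirrors the deployed voice-paced protocol and is what the
rhythm rubric assumes — the optimal cosine is a function of time within
the 6-s round, so an adaptive segmenter would change the meaning of
Index 3.

Offline recordings that start before the first repetition need a start
cue. `detect_start()` takes the first excursion of normalized hip height
below `100 − threshold` (default threshold 10%, enough to exclude jitter
wiggles), finds its trough, and starts the clock half a round (3 s) before
it. Anchoring on the trough rather than on the threshold crossing matters:
the crossing time depends on how deep the squat will turn out to be, while
the trough of a paced repetition sits at the round's midpoint by
construction. The result is clipped at zero.

## The rubric's numerical conventions

* **Band boundaries** follow the printed inequality directions exactly:
  stance bands are lower-closed/upper-open (100% scores 3, 125% scores 2),
  depth bands are upper-closed (exactly 25% scores 2), rhythm bands are
  lower-closed (exactly 60% scores 3).
* **Index 1 aggregation** takes the most frequent per-sample level over
  the round; ties break toward the *lower* score, so ambiguity never
  inflates performance.
* **The rhythm band** "±30% of the optimal curve" is implemented
  additively in normalized units: `|Rhythm(t) − Optimal(t)| ≤ 0.3`, i.e.
  30% of the half-range, the constant-width corridor seen around the
  plotted cosine. A multiplicative band would collapse to zero width where
  the cosine crosses zero and make the mid-descent sample impossible to
  satisfy.
* **Normalization window.** `H_min`/`H_max` for the rhythm rescaling are
  taken within each round, matching the per-repetition rhythm plots; a
  set-wide normalization would let one unusually deep repetition flatten
  the others' rhythm.
* **Undefined samples** are excluded from both the Index-1 mode and the
  rhythm counts (`N_All` counts defined samples only). A round with fewer
  than 50% defined samples is flagged `low_quality` in the diagnostics but
  still scored. A motionless round (`H_max = H_min`) is degenerate:
  Index 3 is 0 rather than 0/0.
* **Empty rounds** (no samples, e.g. a recording cut short) score 0 on
  all indices and are flagged.

The volume law is linear through the origin, `BGM% = total/10 × 100`,
`noise% = 100 − BGM%`. One anchor (8 points → 80%/20%) plus the
qualitative rule that music gets clearer as scores rise fixes the line;
linearity is the least-structured mapping consistent with both, and it
conserves `BGM + noise = 100` exactly on every round.

## The simulator

`simulate_squat()` emulates what the scoring engine actually consumes — a
camera-facing squatter's keypoint stream — with known ground truth. The
hip midpoint follows

```
elev(t) = baseline · [ (1+d)/2 + (1−d)/2 · cos(π t′ / 3) ],   t′ = (t − phase_offset) / tempo_scale
```

so the normalized hip height sweeps 100% → `d·100%` → 100% each round;
knee and shoulder x-separations are fixed by `stance_ratio`; the remaining
13 keypoints ride a simple articulated template (planted feet, rigidly
translating torso, arms held parallel to the ground). The cosine
trajectory is chosen deliberately: with `tempo_scale = 1` the simulated
rhythm sits exactly on the optimal curve, so the maximal-score case is
analytic rather than empirical. Gaussian i.i.d. jitter of `noise_sd` px
models pose-network noise; the generator is seeded and byte-reproducible,
and restores the caller's RNG state.

Defaults are the study conditions: 10 rounds × 6 s at 30 fps, depth
−0.1 (a full-depth squat, 10% below parallel), stance 110% (the optimal
band's interior), standing hip-above-knee distance 100 px and shoulder
width 80 px (plausible for a person a few meters from a webcam at
640 × 480).

What the simulator does **not** emulate: correlated tracking error (real
pose networks lose a limb for whole seconds, drift, or swap left/right),
perspective effects when the subject moves toward the camera,
repetition-to-repetition variability in a human's tempo, and any
biomechanical coupling between joints. Passing tests therefore demonstrate
the *scoring engine's* correctness on well-posed input, not robustness to
every pathology of real video; the confidence-masking/gap machinery is
exercised with synthetic dropouts instead.

Presets bundle one degradation each (`shallow` 60% depth, `narrow` 90%
and `wide` 180% stance, `rushed` half-time cadence, `noisy` 3 px jitter),
each chosen to land unambiguously inside one rubric band so its expected
score is analytic.

## Cohort rules

Respondents group as younger (≤ 39 y), middle (40–59 y), older (≥ 60 y) —
boundaries resolved from the published groups' printed age ranges.
Monthly activity is the product of category midpoints: sessions/month
{over 5/wk: 20, 3–4/wk: 14, 1–2/wk: 6, 1–2/mo: 1.5} × minutes/session
{over 60: 60, 30–50: 40, 10–20: 15, < 5: 5}; the published conversion is
unstated, so these conservative midpoints are documented and configurable,
and published habit percentages are re-summarized from printed counts
rather than re-derived. 240 min/month exactly classifies as `regular` (the
two published phrasings leave the boundary unassigned; assigning it keeps
the dichotomy exhaustive). Percentages are rounded half-up to one decimal,
the convention that reproduces the published table's cells.

## Problem sizes and determinism in the test suite

The suite scores full 60-s sets at 30 fps (1800 frames) for end-to-end
checks and 1–3-round sets where only per-round behavior matters; property
loops run 1000 random rounds for score bounds and 200 random traces
against a per-sample counting oracle, all under fixed seeds. The complete
suite runs in about two minutes on one CPU.

## Known limitations

* Frontal view only; no side-view depth/back-angle analysis.
* Fixed cadence only: a self-paced or variable-repetition set is out of
  scope by design (`detect_start` offers the only adaptivity, a single
  global offset).
* The scoring is rule-based banding, not a learned quality model; scores
  are ordinal, and sums across indices weight stance/depth/rhythm 3:3:4
  by construction.
* Keypoint input is trusted (beyond confidence masking); the pose
  estimator itself is outside the package.
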