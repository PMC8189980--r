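---
title: "Methods: stimulus synthesis, gaze simulation, fixation detection and the statistical battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stimulus synthesis, gaze simulation, fixation detection and the statistical battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plightgaze)
```

`plightgaze` implements a preferential-looking analysis of point-light
biological motion end-to-end: stimulus synthesis with two non-biological
control conditions, synthetic binocular gaze, adaptive-threshold fixation
detection, dynamic region-of-interest (ROI) metrics, and the statistical
battery over the resulting per-participant table. This vignette records the
models, the parameters that matter, and the design choices made where the
design was genuinely open.

## Stimuli

**Procedural walker.** The biological stimulus is a deterministic
sum-of-sinusoids limb model: 15 dots laid out as the major joints of a
figure about 4.6° tall, each oscillating around its base position with two
harmonics of a fundamental gait period (default 100 frames at 120 fps,
i.e. 833 ms). Opposite limbs move in anti-phase, and limb dots receive
larger amplitudes than torso dots. Because only integer harmonics enter,
every coordinate signal is exactly periodic — the property all downstream
stages depend on. A procedural figure was chosen over motion-capture input
deliberately: every computation in the pipeline depends only on
periodicity and dot geometry, so a noiseless, exactly periodic stand-in
makes the validation sharper, and the dot count (never fixed by convention)
defaults to the 15 typical of point-light walkers.

**Periodicity estimation.** `dominant_period()` mean-centres each dot's x
and y signal, correlates the signal with its lag-shifted self over the
overlapping stretch at every integer lag, averages across dots and axes,
and returns the best lag in ms. The search window of 250–2000 ms excludes
lag zero and sub-gait harmonics for human gait at normal speed. For a
periodic signal every multiple of the period attains the maximum
correlation of 1, so ties (within 1e-9) resolve to the shortest lag — the
fundamental. Integer lags keep the estimator exact and trivially
cross-checkable against a brute-force lag scan; no interpolation is done.

**Phase-scrambled control.** Each dot's trajectory is time-shifted by an
independent offset drawn uniformly on ±417 ms — half the 833 ms period, so
an offset can move a dot anywhere within its gait cycle — and the shift is
cyclic with wrap period equal to the gait period. A cyclic (wrap-around)
shift rather than truncation preserves each dot's within-period
frame-to-frame displacement multiset exactly, so local motion is identical
between scrambled and unscrambled stimuli while the global body
configuration is destroyed. Note that R's `round()` uses banker's
rounding (`round(416.5)` is 416); the offset bound uses half-up rounding
to give the conventional 417.

**Rotational control.** Frame 0 is treated as a rigid 2-D point set with
implied depth zero and rotated about the vertical axis at constant speed
`2 * pi / hip_period_ms`, rendering the orthographic x-projection (y
unchanged). The axis passes through the frame-0 centroid: "the spine" of a
dot figure has no canonical coordinates, and the centroid is the
reproducible proxy. No depth foreshortening is simulated. The first
rendered frame equals the biological first frame, so the initial view is
comparable across conditions.

**Trial sets.** 60 four-second trials in 6 blocks; the biological side is
exactly counterbalanced (30 left / 30 right); each clip is horizontally
centred in its half of the screen (quarter-width offset, about 12.1°, so
the two 3.7°-dilated figures can never overlap); onsets are spaced by the
clip duration plus a uniform 1.5–2 s inter-stimulus gap. The control type
per trial (scrambled vs. rotational) is drawn per `control_mix`
(default 0.5).

## Screen geometry

Degrees of visual angle convert to pixels linearly:
`px = deg * distance_cm * tan(1°) / cm_per_px`, with the pixel pitch from
the display diagonal (default 23-inch 1920 × 1080 viewed from 60 cm, about
39.5 px/deg). The small-angle convention is adequate over the ±13° extent
the stimuli occupy.

## Synthetic gaze

The generator emits what the analysis assumes and nothing more: an
alternating fixation/saccade process sampled at 30 Hz.

- Within each trial the first on-ROI fixation begins at onset plus a
  truncated-normal latency (truncation at one sample interval: a latency
  cannot precede onset). Before it — and between trials — the participant
  fixates the screen centre, where the inter-stimulus attention-getter
  sits.
- Every on-stimulus fixation is allocated to the biological side with
  probability `p_bio`, the side decided *per fixation*, which is how
  looking time accrues in preferential-looking data. Fixation targets are
  randomly chosen dots of the allocated side (plus 0.3° jitter); fixation
  durations are gamma (shape 4, mean 300 ms); saccades last one sample
  interval.
- Tracking loss arrives in alternating geometric-length runs; untracked
  runs have mean `1 / dropout_run_geometric_p` (default 3 samples) and
  tracked-run lengths are set so the long-run tracked fraction equals
  `p_valid`. Dropout is shared between the eyes, as tracking loss is in
  practice binocular.
- Both eyes receive independent Gaussian positional noise (default 0.3°
  per axis, typical of remote 30 Hz trackers).
- Between-participant heterogeneity: each participant draws an individual
  `p_bio` (SD 0.085), `p_valid` (SD 0.08) and latency mean (SD 150 ms)
  around the group preset, truncated to their valid ranges. The group
  presets fix only means; these dispersions are free choices, set once so
  that the default two-group design yields a preference-difference
  Cohen's *d* near the reference value of 0.87. A preset `p_valid` of
  exactly 1 is kept exact (no downward heterogeneity), so lossless
  configurations really are lossless.
- The generator also writes a ground-truth event log — true on-ROI
  fixation intervals with sides, and the true first-fixation latency per
  trial — because parameter-recovery testing needs an internal truth
  channel.

Group presets carry the reference group means: ASD-like `p_bio` 0.545,
`p_valid` 0.800, latency mean 649.1 ms; TD-like 0.619, 0.892, 521.3 ms.
Cohorts default to 121 ASD-like and 40 TD-like participants with matched
covariate distributions (ASD-like: mean age 14.6 y, 76% male, IQ composite
mean 98.5 SD 20 truncated to 60–136, plus 29 opaque symptom subscale
scores; TD-like: mean age 16.4 y, 65% male). Per-participant seeds derive
from the master seed by a counter-based rule
(`(master * 1000003 + i) mod (2^31 - 1)`), so recordings are reproducible
and uncoupled.

What the generator does **not** emulate: main-sequence saccade dynamics,
microsaccades, smooth pursuit, calibration error, head movement, or any
age/symptom dependence of gaze (symptom scores are independent noise by
default, which is what makes the null calibration of the correlation grid
testable). Passing tests therefore show that the pipeline recovers the
parameters of data *with the assumed structure* — not that the model
captures every property of real infant- or clinic-grade recordings.

## Fixation detection

Detection follows the binocular-individual-threshold idea: per-eye
adaptive velocity cutoffs, AND-gated across eyes.

- Speeds are backward differences between consecutive tracked samples in
  deg/s; velocity is never interpolated across untracked gaps (that would
  fabricate data at 30 Hz).
- The cutoff per eye iterates `mean + 3 SD` of sub-cutoff speeds from all
  defined speeds until the relative change drops below 1e-3. With
  fixational samples dominating the stream, the iteration settles between
  the fixation and saccade speed modes; for a degenerate (constant) speed
  distribution it converges immediately at that constant.
- A sample is fixational iff both eyes' local speeds are defined and below
  their cutoffs. The local speed is the *backward* difference (with a
  forward-difference fallback where the previous sample is untracked).
  This matters: a symmetric `min(backward, forward)` rule lets the flight
  sample of a one-sample saccade slip under the threshold whenever it
  lands near either endpoint, silently merging fixations across large gaze
  shifts — in testing this produced fixations spanning trial boundaries.
  With the backward rule, a large shift always yields at least one
  super-threshold sample, because the flight and landing samples cannot
  both be slow.
- Maximal fixational runs tolerate internal untracked runs of at most 3
  samples; runs with fewer than 3 tracked samples are discarded (both
  counts are the conventional settings for 30 Hz data). Untracked samples
  inside a fixation bridge it but contribute neither position nor looking
  time. The centroid is the mean tracked cyclopean (two-eye average)
  position — a single position is what the ROI test needs, and averaging
  halves independent noise.

A consequence of 30 Hz sampling worth knowing: saccades between dots of
the *same* figure (< 1° or so) are slower than the adaptive threshold and
are absorbed into the surrounding fixation. Cross-side and
centre-to-stimulus shifts (12–24°) always split. Absorbing same-side
micro-shifts adds a small amount of looking time to the side being viewed
and is shared by any velocity-based detector at this rate.

## Dynamic-ROI metrics

Each side's ROI is the union of 3.7° circles centred on that side's dots
in the stimulus frame active at the sample's time
(`floor((t - onset) * fps / 1000)`). A position inside both ROIs (possible
only if the figures were close) takes the side of the nearest dot, with
exact ties resolved to the biological side. Times outside the presentation
window classify as neither.

- **Total valid time (%)** — share of samples within presentation windows
  with at least one eye tracked and the cyclopean position on-screen; the
  complement of data loss. Off-screen samples count against it.
- **Preference for biological motion (%)** — looking time accrues per
  tracked fixation sample, classified at that sample's time and position;
  the metric is the pooled ratio `100 * t_bio / (t_bio + t_nonbio)` across
  all trials (a ratio of total times, not a per-trial average), flagged
  undefined when no on-ROI time exists.
- **First-fixation metrics** — a fixation is assigned to an ROI when at
  least half of its tracked samples fall inside it (a rule needed because
  dots can move out from under a fixation mid-event). Per trial, the first
  fixation assigned to each side defines that side's latency as fixation
  start minus onset (the fixation is the unit of looking, so its start —
  not the first in-ROI sample — is the anchor). The share of trials whose
  earliest ROI fixation is biological gives the first-fixation percentage;
  each latency metric averages only trials where that side was fixated at
  all.

No centre-of-screen gating is applied at onset, mirroring the acquisition
protocol's own behaviour. Note one composition effect inherent to the
per-side latency metrics: with per-fixation allocation, the first fixation
of a trial lands on the non-preferred side with probability
`1 - p_bio`, so each side's first-fixation latency includes trials where
the other side was visited first and is therefore larger than the
generator's trial-level latency parameter. The generator preset calibrates
the trial's *first* on-ROI fixation; recovery of that parameter is tested
through the truth log, and the measured per-side latency is validated
against truth in a near-one-sided configuration.

## Statistical battery

- **Group ANCOVA** per metric: `metric ~ group + age + gender`, no
  interactions. The group F statistic uses the partial sum of squares
  (full vs. group-free model); partial η² is
  `SS_group / (SS_group + SS_residual)`. Cohen's *d* uses raw group means
  and the pooled SD — not covariate-adjusted means — signed second factor
  level minus first; raw *d* is the reproducible default when the
  adjustment convention is unstated. Rows with missing values are excluded
  and counted.
- **Signed-rank tests** (against the 50% chance level, and paired for the
  two latencies) drop zero differences, use mid-ranks for ties, and take
  two-sided p-values from the normal approximation with continuity and tie
  corrections — standard at group sizes of 40–121. `stats::wilcox.test`
  implements exactly these conventions; the test suite checks it against
  an exhaustive sign-enumeration oracle for n ≤ 12 in the moderate-p
  regime (exact p in 0.05–0.95), where the approximation is within 10%
  relative error. In the far tail the relative error of any normal
  approximation exceeds that, which is immaterial at the p-levels where
  decisions happen. All-zero differences flag a degenerate result with
  p = 1.
- **Partial Spearman correlations**: ranks of x, y and each covariate
  (gender as a numeric code), least-squares residualization of the x and y
  ranks on the covariate ranks (with intercept), correlation of residuals,
  and a t reference with `n - 2 - k` degrees of freedom. With no
  covariates this is ordinary Spearman; the suite cross-checks the
  implementation against the precision-matrix identity on the rank
  correlation matrix.
- **Benjamini–Hochberg** step-up adjustment (via `stats::p.adjust`)
  applies to exactly the five primary group tests at FDR 5%; all other
  p-values are reported raw, matching the exploratory framing.
- **Severity tertiles**: scores ranked stably (ties break by input
  position), split at thirds with remainders allocated to the more severe
  groups — sizes (40, 40, 41) at n = 121. **IQ strata** are closed
  intervals 60–84 / 85–115 / 116–136.
- `run_full_battery()` assembles the report: five BH-adjusted group
  effects, chance-level and paired tests per group, the 29 × 3 severity
  grid (cells with fewer than 6 participants flag NA rather than fail),
  IQ strata sizes with per-stratum group ANCOVAs, and the 5 × 29 = 145
  partial-correlation grid.

## Numerical and degenerate-input choices

- Threshold iteration stops at relative change < 1e-3 or 200 iterations;
  constant speeds converge in one step.
- Autocorrelation argmax ties resolve to the shortest lag within 1e-9.
- Empty recordings, all-invalid streams, and zero on-ROI time return empty
  results or NA flags rather than errors; malformed files and non-monotone
  timestamps fail fast with the offending row named.
- All randomness flows through per-call local RNG streams, so library
  calls never disturb the caller's `.Random.seed` and every artifact is
  reproducible from its recorded seed.

## Problem sizes used in validation

The test suite exercises full-scale cohort recovery — the unbiased design
at n = 40 and the calibrated presets at the reference sizes (n = 121 and
n = 40), five seeded replicates each, 60 trials per participant — plus
smaller fixtures (10–20 trials, 5–32 participants) for unit and property
tests; these sizes keep the whole suite at a few minutes on one CPU while
the cohort means carry standard errors a few tenths of a percentage point.
The acceptance script reruns the full-scale conditions from scratch.

## Known limitations

- The walker is a stylised periodic figure; conclusions about stimulus
  *content* (naturalness, configural cues) are outside scope.
- The gaze model has no smooth pursuit; a viewer tracking a moving dot is
  represented as a static fixation plus noise, which is adequate at 30 Hz
  and 0.5–1° dot excursions but not for faster stimuli.
- At 30 Hz, velocity-based detection cannot resolve saccades shorter than
  one sample interval or smaller than the noise floor; detector recall is
  therefore evaluated against fixations of at least four samples, and
  fixations mostly swallowed by tracking dropout (fewer than three tracked
  samples) are not recoverable by any rule-respecting detector.
- Severity and correlation analyses treat symptom scores as opaque
  numbers; no instrument semantics are modelled.
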