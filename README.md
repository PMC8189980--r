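# plightgaze

Preferential-looking analysis of point-light biological motion, as a tested,
reusable R pipeline.

In a preferential-looking paradigm, two dynamic point-light displays (PLDs)
are shown side-by-side — one depicting biological motion (a walking human
rendered as dots at the major joints), the other a motion-matched
non-biological control — while a remote eye tracker records binocular gaze
at 30 Hz. The share of looking time allocated to the biological side indexes
an attentional bias that is reduced in autism spectrum disorder (ASD)
relative to typically developing (TD) viewers. `plightgaze` implements every
stage of that analysis so the design can be studied, validated and
power-analysed end-to-end on synthetic cohorts, with no access-restricted
clinical data:

- **Stimuli** (`generate_walker`, `phase_scramble`, `rotational_control`,
  `make_trial_set`): a procedural, exactly periodic point-light walker; a
  phase-scrambled control that cyclically time-shifts each dot by an offset
  drawn uniformly on ±417 ms (half the 833 ms gait period), preserving each
  dot's local motion while destroying global form; and a rotational control
  that spins the first frame about the vertical axis. Dominant periodicity
  is estimated by averaged autocorrelation (`dominant_period`). Trial sets
  are 60 four-second clips in 6 blocks with the biological side exactly
  counterbalanced (30 left / 30 right).
- **Synthetic gaze** (`simulate_cohort`, `simulate_participant`): a seeded
  generator producing 30 Hz binocular recordings with an alternating
  fixation/saccade process, per-fixation biological-side allocation
  `p_bio`, geometric-run tracking dropout calibrated to a target valid
  fraction `p_valid`, per-eye positional noise, and a ground-truth event
  log for parameter-recovery testing. Group presets carry the reference
  means (ASD-like: `p_bio` 0.545, `p_valid` 0.800; TD-like: 0.619, 0.892).
- **Fixation detection** (`detect_fixations`): binocular-individual
  adaptive velocity thresholds (iterated mean + 3 SD per eye, AND-gated
  across eyes), with the two count rules — at least 3 tracked samples per
  fixation, at most 3 consecutive untracked samples bridged inside one.
- **Dynamic-ROI metrics** (`participant_metrics`): per-frame regions of
  interest are unions of 3.7° circles around each side's dots; the five
  per-participant metrics are total valid time (%), preference for
  biological motion (%), first-fixation share on biological motion (%),
  and the first-fixation latencies on each side (ms).
- **Statistics** (`run_full_battery`): per-metric group ANCOVA
  (`metric ~ group + age + gender`) with partial η² and Cohen's *d*,
  Benjamini–Hochberg adjustment over the five primary tests (FDR 5%),
  Wilcoxon signed-rank tests against the 50% chance level, paired latency
  tests, severity tertiles (29 symptom subscales × mild/moderate/severe),
  IQ strata (60–84 / 85–115 / 116–136), and the 5 × 29 partial Spearman
  correlation grid with age, gender and IQ as covariates.

## Worked example

```r
library(plightgaze)

walker <- generate_walker(duration_s = 4, fps = 120,
                          gait_period_frames = 100, n_points = 15, seed = 1)
walker
#> <point_light_clip> 'walker_p100_s1': 480 frames x 15 points @ 120 fps (biological, 4.00 s)
dominant_period(walker)
#> [1] 833

trials <- make_trial_set(trial_set_config(seed = 1), walker)
trials
#> <trial_set> 60 trials in 6 blocks (bio left/right: 30/30), period 833 ms

cfg <- cohort_config(n_asd = 20, n_td = 12,
                     trial_config = trial_set_config(n_trials = 20,
                                                     n_blocks = 2, seed = 1),
                     seed = 1)
cohort  <- simulate_cohort(cfg)
metrics <- cohort_metrics(cohort)   # simulate -> detect -> dynamic-ROI metrics
aggregate(cbind(total_valid_pct, preference_bio_pct) ~ group,
          data = merge(cohort$participants, metrics),
          FUN = function(x) round(mean(x), 1))
#>      group total_valid_pct preference_bio_pct
#> 1 ASD-like            78.2               54.0
#> 2  TD-like            90.1               58.9

report <- run_full_battery(metrics, cohort$participants, cohort$symptom_scores)
report
#> <plight_report>
#>   group effects: 5 metrics (BH-adjusted)
#>     total_valid_pct      d =   1.61  eta_p^2 = 0.409  p_adj = 0.000709
#>     preference_bio_pct   d =   0.44  eta_p^2 = 0.047  p_adj = 0.315
#>     first_fix_bio_pct    d =  -0.05  eta_p^2 = 0.000  p_adj = 0.986
#>     latency_bio_ms       d =  -0.83  eta_p^2 = 0.168  p_adj = 0.0611
#>     latency_nonbio_ms    d =  -0.61  eta_p^2 = 0.109  p_adj = 0.125
#>   severity grid: 87 cells; correlation grid: 145 cells
```

The group means read as: the ASD-like preset tracks the screen less (78.2%
vs. 90.1% valid time) and allocates a smaller share of its on-stimulus
looking time to biological motion (54.0% vs. 58.9%) than the TD-like
preset. Cohen's *d* is signed TD-like minus ASD-like; at this demo size
(20 + 12 participants, 20 trials) only the valid-time difference survives
the Benjamini–Hochberg adjustment. At the reference design
(121 + 40 participants, 60 trials) the preference effect is reliably
recovered too — that is what the acceptance script measures.

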