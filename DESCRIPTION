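Package: plightgaze
Title: Preferential-Looking Analysis of Point-Light Biological Motion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for preferential-looking eye-tracking studies
    of biological motion. Synthesizes periodic point-light walker stimuli
    together with phase-scrambled and rotational non-biological controls,
    estimates stimulus periodicity by autocorrelation, simulates seeded
    binocular gaze recordings for parameterized cohorts, detects fixations
    with per-individual adaptive velocity thresholds, computes dynamic
    region-of-interest eye-movement metrics (total valid time, preference
    for biological motion, first-fixation share and latencies), and runs
    the associated statistical battery: group ANCOVA with Cohen's d and
    partial eta-squared, Wilcoxon tests against chance, paired latency
    tests, severity tertiles, IQ strata, partial Spearman correlations,
    and Benjamini-Hochberg adjustment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
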