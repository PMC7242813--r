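Package: buccalmotor
Title: Motor-Neuron Recruitment Analysis for Aplysia Swallowing Under Load
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for multichannel extracellular nerve, EMG and
    force recordings of Aplysia californica swallowing behavior: spike
    extraction with window discriminators, burst identification from
    instantaneous-firing-frequency thresholds, five-stage segmentation of the
    force record of loaded swallows, piecewise-linear time normalization with
    median/quartile aggregation across swallows, and the paired statistical
    battery (one-tailed paired t, paired Hotelling's T-squared with Bonferroni
    post hoc tests, Shapiro-Wilk gating into an exact Wilcoxon signed-rank
    test, pooled Cohen's d, linear regression). Includes a seeded synthetic
    recording generator with ground truth so the full pipeline can be
    exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
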