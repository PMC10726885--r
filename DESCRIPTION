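Package: qeegnorm
Title: Quantitative EEG Normative Z-Score Biomarkers for Migraine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline from raw 19-channel resting-state EEG to
    quantitative EEG (QEEG) biomarkers of migraine: acquisition filtering and
    down-sampling, automated artifact rejection, 2-second epoch FFT absolute
    power on a 0.5-30 Hz grid with split-half and test-retest reliability
    gating, z-scoring of band power against an age-stratified normative
    database, the supra-threshold electrode-count biomarker (z > 1.96),
    pre/post-treatment monitoring, and the cohort statistical layer
    (Mann-Whitney, Wilcoxon signed-rank, chi-square/Fisher, crude and
    multivariable logistic odds ratios). Includes a calibrated synthetic EEG
    and cohort generator so every stage is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
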