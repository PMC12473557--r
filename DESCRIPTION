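Package: neowear
Title: Feasibility, Safety and Accuracy Evaluation of Wireless Vital-Sign
    Sensors Against a Wired Reference
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A validation framework for wireless neonatal vital-sign
    monitors evaluated against a wired bedside reference. Provides a data
    model for paired dual-device recordings (photoplethysmogram, SpO2 and
    FiO2 channels with explicit missingness, care-activity annotations and
    device alert flags), resampling and cross-correlation synchronization,
    signal-coverage and gap analysis with spectral signal-to-noise
    estimation and decision-tree gap-cause attribution, paired Neonatal
    Skin Condition Score statistics with configurable Wilcoxon signed-rank
    conventions, sample-to-sample agreement metrics (Bland-Altman bias and
    limits of agreement, mean absolute error, margin of error) with a
    modified Clarke error grid for SpO2 under neonatal alarm thresholds,
    and a seeded synthetic dual-device generator with ground truth for
    closed-loop parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    arrow,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
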