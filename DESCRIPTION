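Package: vbmon
Title: Longitudinal Vocal-Biomarker Monitoring of Asthma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for prospective vocal-biomarker asthma
    monitoring studies. Takes per-session app records (paired
    respiratory-responsive vocal-biomarker scores, peak expiratory flow
    readings, well-being reports) together with monthly Asthma Control
    Test scores and enrollment data, applies the two-stage score quality
    control, estimates peak-flow personal bests with traffic-light zone
    classification, labels each session's respiratory state, derives
    per-participant reference scores and a normalized high-risk
    threshold, and computes prevalence risk ratios with log-scale
    confidence intervals for respiratory states and asthma-control
    levels. Includes engagement and retention metrics, within-participant
    change-score transition tables, and a seeded synthetic-cohort
    simulator that emulates the study's data structure so the full
    pipeline can be exercised and calibrated without access to study
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
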