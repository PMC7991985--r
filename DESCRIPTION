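Package: screensca
Title: Smartphone Screen-Time Metrics, Symptom Aggregation, and Specification-Curve Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for digital-phenotyping studies that relate
    objective smartphone screen-time metrics to psychiatric symptomatology.
    Converts raw screen on/off event logs into sessions and per-day metrics
    (screen time, session time, number of sessions, habitual checks under 15
    seconds), aggregates repeated smartphone surveys (PHQ-9 mood, GAD-7
    anxiety, sleep, sociability) and smartphone cognition scores to the daily
    grid, applies consecutive-day and survey-based cohort inclusion filters,
    and runs the study analyses: Spearman/FDR screening of baseline cognition,
    pooled multivariate regression of longitudinal cognition on screen
    metrics, a from-scratch specification-curve engine over variable, model,
    covariate and subgroup choices, and per-participant symptom-on-screen-time
    regressions. Ships a synthetic-cohort generator with known ground truth so
    every stage is testable without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    readr,
    lubridate,
    ggplot2,
    stats,
    utils,
    withr,
    jsonlite
Suggests:
    patchwork,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
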