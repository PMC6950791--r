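Package: wlaqfit
Title: Questionnaire-Based Estimation of Maximal Oxygen Consumption in Workers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the modified Worker's Living Activity-time Questionnaire
    (m-WLAQ), a 0-44-point physical-activity composite alongside four domains
    of daily sitting time, and turns the scores into non-exercise estimates of
    maximal oxygen consumption (VO2max). Provides ordinary-least-squares
    prediction models with PRESS leave-one-out cross-validation (R2p, SEEp),
    constant-error subgroup validation, and test-retest reliability via the
    intraclass correlation coefficient with F-based confidence intervals.
    Ships the published prediction equations ready for batch use, and a
    calibrated synthetic-cohort generator so the whole pipeline runs without
    access to the original study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
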