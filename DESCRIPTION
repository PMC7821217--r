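Package: pultriage
Title: Triage and External Validation of Outcome Prediction Models for
    Pregnancy of Unknown Location
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the multinomial risk models (M4, M6 with and without
    progesterone) and the two-step triage strategy (2ST) used to classify
    pregnancies of unknown location (PUL) as low or high risk of ectopic
    pregnancy, together with the machinery needed to validate such models
    in multicentre cohorts: binary and conditional-risk AUC, the polytomous
    discrimination index, mixed-effects calibration intercepts and slopes,
    smooth calibration curves, Net Benefit and decision curves, random-effects
    meta-analysis with prediction intervals, protocol-driven missingness
    rules, multiple imputation by chained equations with Rubin pooling, and
    a multi-centre synthetic cohort generator for testing every pipeline
    stage without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    metafor,
    nnet,
    purrr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    pROC,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
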