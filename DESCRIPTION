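Package: neorisk
Title: Epidemiological Neonatal Mortality Risk Score from Vital-Statistics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and validates an epidemiological risk score for neonatal
    death (0-27 days) from routinely collected birth-certificate data linked to
    municipal health-system indicators. Implements empirical severity grading of
    congenital anomalies (ICD-10 Chapter XVII) by observed lethality, ecological
    screening of municipal indicators against a proxy neonatal mortality rate,
    random-intercept multilevel logistic modelling, conversion of adjusted odds
    ratios into 1-10 integer score points via ln(OR) scaling, risk-group
    stratification, and discrimination/calibration validation (ROC/AUC, Youden
    index, per-cutoff performance, grouped calibration, McFadden pseudo-R2).
    Includes a synthetic birth-cohort generator emulating Sao Paulo State
    vital-statistics structure so the full pipeline is testable without
    access-restricted registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    readr,
    rlang,
    jsonlite,
    lme4,
    pROC,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    car,
    yaml,
    optparse
Config/testthat/edition: 3
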