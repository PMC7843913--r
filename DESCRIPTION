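Package: comascore
Title: Coma Severity Scores and Paired Diagnostic-Accuracy Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the INCNS (Inflammation, Nutrition, Consciousness,
    Neurological function, Systemic function) severity score for comatose
    neurocritical-care patients together with the standard comparator scales
    (Glasgow Coma Scale, FOUR, APACHE II), the cohort-construction rules used
    to validate them (coma eligibility, worst-value windows, outcome
    dichotomization), and the paired diagnostic-accuracy statistics needed for
    score comparison: empirical ROC/AUC with DeLong confidence intervals and
    paired tests, Youden-index cut-offs, confusion-matrix metrics, McNemar
    tests, and a generalized score test for paired predictive values. A
    seeded latent-severity simulator generates synthetic comatose cohorts with
    nested binary outcomes so the whole pipeline is testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    generics,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
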