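Package: romadx
Title: Diagnostic Evaluation of the ROMA Index for Adnexal Masses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for preoperative triage of adnexal masses with serum
    biomarkers. Computes the Risk of Ovarian Malignancy Algorithm (ROMA)
    predictive index and percentage from CA125 and HE4 with menopause-specific
    coefficients, builds empirical ROC curves with Youden-index optimal
    cutoffs, and evaluates markers with a full diagnostic-test metric suite
    (sensitivity, specificity, predictive values, likelihood ratios,
    diagnostic odds ratio, Cohen's kappa) with 95% confidence intervals
    (Wilson score intervals for proportions). Includes baseline group
    comparisons (Mann-Whitney, chi-square, Fisher exact), a calibrated
    synthetic-cohort generator for testing the pipeline without patient data,
    and a stratified end-to-end analysis driver with deterministic reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
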