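Package: latentcog
Title: Latent-Variable Brain-Cognition Analysis and Treatment-Outcome
    Prediction for Multi-Site Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for multi-site brain-cognition
    studies in late-life treatment-resistant depression: participant- and
    feature-level quality-control filters, empirical-Bayes location/scale
    site harmonization with protected covariates, partial least squares
    (PLS) regression linking brain feature matrices to cognitive test
    batteries with permutation tests of model significance and bootstrap
    ratios for loading robustness, leave-one-site-out generalizability of
    composite cognition, and remission prediction via iterated nested
    cross-validated elastic-net logistic regression with stability
    selection. Includes a multi-site synthetic-cohort generator with known
    latent ground truth for parameter-recovery testing, and a single-call
    pipeline orchestrator with deterministic seed management.
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
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mixOmics,
    pROC,
    sva,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
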