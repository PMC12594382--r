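Package: forestfill
Title: Iterative Random Forest Imputation for Prediction Settings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single imputation of mixed continuous and categorical data by
    iterative chained random forests with a unified out-of-bag normalized
    mean squared error (NMSE) convergence criterion. Per-variable, per-
    iteration forest models are persisted so that new observations -- down
    to a single row -- can be imputed at prediction time by replaying the
    stored models. Includes mean/mode and linear-regression baseline
    imputers with the same fit/predict contract, MCAR/MAR/MNAR amputation
    mechanisms for missingness simulation, a calibrated generator of
    correlated-Gaussian datasets with a binary logistic outcome, and a
    benchmark harness that splits, amputes, imputes and evaluates
    prediction models on imputed data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
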