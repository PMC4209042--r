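Package: lassomi
Title: Lasso Prediction Models and Bootstrap Validation with Multiply Imputed Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds penalized (lasso) linear prediction models on multiply
    imputed data and internally validates them with Harrell's bootstrap
    optimism procedure. Penalties are tuned per imputed data set on a grid by
    bootstrap-corrected mean squared error, with both the optimal ("best") and
    a stronger 3 percent tolerance penalty; coefficients are pooled by
    averaging across imputations. Four resampling schemes for handling the
    imputed data sets during the optimism bootstrap are provided, together
    with calibration diagnostics (calibration slope, decile table), uniform
    shrinkage recalibration, chained-equations imputation with predictive mean
    matching and logistic draws, and a Monte Carlo simulation framework that
    quantifies the bias of each resampling scheme against external optimism.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    withr,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
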