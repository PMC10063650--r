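Package: wstabsel
Title: Weighted Stability Selection for High-Dimensional Binary Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Variable selection for binary outcomes in high-dimensional
    settings (p >> n) by complementary-pairs stability selection with
    AUC-based weighting of resampling iterations. Each complementary pair
    contributes the intersection of its two half-sample cross-validated
    logistic-LASSO supports, screened by a Wald test in a full-data refit;
    iterations are weighted by the min-max rescaled in-sample AUC of the
    screened model, and variables are selected by a threshold on the mean
    weighted frequency. Also provides the Shah-Samworth complementary-pairs
    stability selection baseline with per-family error-rate control
    (including the unimodal and r-concave error bounds), plain
    cross-validated LASSO, a synthetic-data generator for multivariate
    Gaussian predictors with calibrated event prevalence, selection-quality
    and selection-stability metrics (TPR, PPV, Jaccard, Ochiai, Dice,
    Mann-Whitney AUC), and a scenario runner for simulation studies and
    train/validation/test workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    readr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
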