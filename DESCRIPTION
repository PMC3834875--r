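Package: stageval
Title: Evaluation of Prostate Cancer Staging Prediction Models
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates prostate-cancer surgical cohorts with realistic
    clinical covariate structure (PSA, clinical stage, biopsy and
    prostatectomy Gleason score, age, family history, pathological stage),
    fits staging classifiers (logistic regression, random forests, k nearest
    neighbours and univariate clinical-variable models) under 5-fold
    cross-validation, and evaluates them with a three-pronged framework:
    discrimination metrics (sensitivity, specificity, Youden index, PPV,
    NPV, Brier score, AUC), Loess-smoothed calibration curves with binned
    Wilson error bars, and decision-curve analysis of net benefit against
    treat-all and treat-none reference strategies. Also applies Partin-style
    published lookup tables to a cohort for comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    class,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
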