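Package: manugrip
Title: Detecting Insincere Grip Effort from Manugraphy Load-Distribution Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating the sincerity of cylinder-grip force tests
    from the hand's load-distribution pattern. Provides a data model for
    manugraphy records (total grip force plus the percent contribution of
    seven anatomical areas), segmentation of raw pressure-sensor grids,
    a synthetic-cohort simulator replicating a 54-subject bimanual
    maximal/submaximal study design, the conventional bimanual
    exceedance-count classifier with ROC-based cut-off selection, a
    cross-validated machine-learning harness (random forest, linear SVM,
    gradient boosting, XGBoost), and diagnostic-performance reporting with
    exact binomial and DeLong confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    randomForest,
    e1071,
    xgboost,
    rpart,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
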