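Package: crispgait
Title: Correlation-Filtered RFE and SMOTE Pipeline for Gait-Based
    Parkinson's Disease Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Turns raw vertical ground-reaction-force (VGRF) walk
    recordings in the PhysioNet gait-database text dialect into per-cycle
    spatiotemporal gait features, curates the feature panel by Pearson
    correlation pruning with mutual-information tie-breaking followed by
    recursive feature elimination with a 100-tree random forest, balances
    classes with SMOTE inside training folds, and evaluates a five-model
    classifier suite (KNN, decision tree, random forest, gradient
    boosting, XGBoost) under cycle-level and subject-wise cross-validation
    for binary Parkinson's disease detection and multiclass Hoehn-Yahr
    severity grading. Includes a synthetic VGRF cohort simulator with
    ground-truth gait events so the full pipeline is testable without the
    clinical dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    caret,
    jsonlite,
    pROC,
    randomForest,
    rpart,
    stats,
    tools,
    utils,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
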