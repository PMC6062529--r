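Package: progpipe
Title: Automated Construction of Clinical Prognostic Model Pipelines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated configuration of clinical prognostic pipelines
    (imputation, feature processing, classification, calibration) by
    decoupled Gaussian-process Bayesian optimization of a
    precision-oriented clinical utility (the mean of the area under the
    precision-recall curve and the average precision), posterior
    probability-of-best ensembling of the explored pipelines, and a
    post-hoc associative-classifier interpreter that maps conjunctions of
    discretized clinical conditions to clinician-defined risk strata.
    Includes cohort-assembly machinery for registry-style patient data
    (flow-chart filters, composite endpoints, CFTR genotype encoding,
    baseline-table statistics, recalibration) and a synthetic
    registry-like data generator so the whole workflow runs without
    access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    ranger,
    xgboost,
    glmnet,
    rpart,
    e1071,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
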