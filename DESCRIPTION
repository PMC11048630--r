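Package: vmatqa
Title: Multi-Branch Neural Network Prediction of VMAT Patient-Specific
    QA Gamma Passing Rates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts gamma passing rates (GPR) for volumetric modulated
    arc therapy (VMAT) patient-specific quality assurance from tables of
    plan-complexity metrics.  Implements a multi-branch neural network
    (MBNN) with separate feature-extraction branches for Linac-parameter
    metrics, plan-property metrics and the full metric set, late fusion
    of branch features, per-branch sigmoid prediction heads combined by
    fixed convex weights, and a composite squared/absolute-error loss
    trained by mini-batch stochastic gradient descent.  Ships a 47-metric
    schema with validation, leakage-free preprocessing (standardization
    and one-hot encoding fit on the training partition), a synthetic
    plan-table generator with known ground truth for end-to-end testing,
    TG-218 tolerance/action-limit classification, a measurement-anomaly
    audit workflow, and seed-reproducible baseline and ablation
    harnesses (SVM, random forest, k-nearest-neighbour, lasso; branch
    and hidden-width ablations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    e1071,
    randomForest,
    glmnet,
    caret
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
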