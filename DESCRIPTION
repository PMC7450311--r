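Package: metaconn
Title: Individual Metabolic Brain Networks from FDG-PET and
    Connectome-Based Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Constructs individual (single-subject) metabolic brain networks
    from atlas-parcellated FDG-PET volumes by estimating each region's
    voxel-intensity probability density with kernel density estimation
    (solve-the-equation plug-in bandwidth) and scoring every region pair with
    a similarity derived from the symmetric Kullback-Leibler (Jeffreys)
    divergence, KLS = exp(-D). The resulting 90 x 90 connectomes feed a
    connectome-based predictive modeling pipeline: repeated stratified
    50/50 splits, inner cross-validated LASSO feature selection, linear SVM /
    L1 logistic regression / random forest classification, classification
    metrics with ROC/AUC and the Hosmer-Lemeshow calibration test, and
    Z-score identification of hub regions carrying discriminative
    connectivity. A synthetic-cohort generator with planted group effects
    makes the whole pipeline testable without access-restricted PET data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    glmnet,
    e1071,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
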