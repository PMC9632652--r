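Package: mselm
Title: Multisource Distribution-Adaptive Feature Learning with Regularized
    Extreme Learning Machines
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for binary image classification under multisource domain
    shift. A small convolutional feature-extraction network aligns each
    source domain with the target domain through a Wasserstein-weighted
    combination of marginal and class-conditional maximum mean discrepancy,
    trains an ensemble of softmax sub-predictors, and exports pooled deep
    features. Downstream, minimum-redundancy maximum-relevance (mRMR)
    feature selection feeds an extreme learning machine whose output
    weights are solved by pseudoinverse, a ridge closed form, or an
    L1-penalized coordinate-descent solver. Includes exact empirical
    Wasserstein distances via a min-cost-flow transport solver, kernel MMD
    estimators, ROC/AUC and confusion-matrix metrics, kernel-density
    distribution comparison, and a synthetic multi-domain generator with
    independently controllable marginal and conditional shifts.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    Rcpp,
    jsonlite,
    yaml,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
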