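Package: oclab
Title: One-Class Nearest-Neighbor Classification for Imbalanced Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for one-class classification of severely imbalanced
    tabular data, built around nearest-neighbor novelty detection. Provides
    the OCNN family of classifiers (11NN, 1KNN, J1NN, JKNN), K-means with
    outlier removal (KMOR) for simultaneous clustering and outlier
    detection, proxy-outlier based optimization of the neighbor counts
    (J, K) and the acceptance threshold (theta), and a location-based
    nearest-neighbor classifier (LBNN) that accepts a test point when its
    distance to a cluster's nearest member falls below a percentile of
    that member's within-cluster distances. Includes a KEEL '.dat' reader,
    forward stepwise feature selection by AUC, G-means centric evaluation
    metrics, a seeded synthetic-data generator with planted outliers, and
    a repeated stratified cross-validation harness with optional wrapped
    baselines (one-class SVM, logistic regression, SVM, random forest).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    e1071,
    randomForest,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
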