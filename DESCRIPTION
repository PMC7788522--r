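Package: mediansupp
Title: Median-Supplement Balancing for Imbalanced Binary Classification
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Balances imbalanced two-class training tables by generating
    synthetic minority-class instances from per-attribute medians scaled by
    uniform random factors, and couples the balanced data to Gaussian naive
    Bayes and random forest classifiers. Includes an evaluation protocol
    (classification rate, confusion matrices, stratified repeated k-fold
    cross-validation with in-fold balancing, Mann-Whitney comparison of
    classification-rate samples), synthetic fixture generators for
    expression-like and physicochemical-feature-like datasets, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
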