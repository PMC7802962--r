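Package: coffeeDiscrim
Title: Multi-Trait Environment Discrimination for Coffee Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Compares statistical and machine-learning classifiers for
    discriminating coffee production environments and post-harvest
    processing from multi-trait phenotype data. Provides a synthetic
    phenotype generator parameterized by published per-environment trait
    means and standard deviations, repeated proportional stratified k-fold
    cross-validation, eight supervised classifiers (Fisher and Anderson
    discriminant rules, entropy classification tree, bagging, random
    forest, multinomial gradient boosting, multilayer perceptron and
    radial basis function networks) plus an unsupervised Kohonen map,
    apparent error rate evaluation with fold-averaged confusion matrices,
    Scott-Knott grouping of method means, and dual weight-zeroing /
    input-randomization trait importance with relative-importance
    normalization and cutoff-based selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    randomForest,
    stats,
    tree,
    utils,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
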