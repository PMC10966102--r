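Package: flavorbench
Title: Linking Beverage Chemistry to Flavor and Consumer Appreciation with
    Machine Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for predicting sensory profiles and consumer appreciation
    of beer from compound concentration data. Provides preprocessing of
    compound matrices (log-transform selection by Shapiro-Wilk, mean
    imputation, style-stratified splitting, train-set standardization),
    trained-panel score normalization and consistency analysis, consumer
    review filtering and text mining (aspect classification, TFIDF sensory
    enrichment), a ten-family regression benchmark with cross-validated grid
    search, model dissection via impurity importance, exact TreeSHAP
    attributions and partial dependence, in-silico compound spiking plans
    with exact binomial validation tests, and a synthetic-data generator
    with planted ground truth (Gaussian copula chemistry, Hill-type sensory
    response surfaces, biased review corpora) that makes the whole pipeline
    testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    Matrix,
    Rcpp,
    glmnet,
    ranger,
    rpart,
    e1071,
    nnet,
    mixOmics,
    xgboost,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
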