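Package: ecgxai
Title: Decision-Criteria Extraction for ECG-Parameter Classifiers of Reduced Ejection Fraction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for training tabular electrocardiogram (ECG) parameter
    classifiers of reduced left ventricular ejection fraction and for turning
    their per-record Shapley attributions into human-readable decision
    criteria.  Implements exact interventional Shapley attribution (subset
    enumeration, kernel weighted-least-squares, and a fast tree path for
    random forests), PCA-UMAP embedding of attribution space, variational
    Bayesian Gaussian mixture clustering with automatic component pruning,
    the per-cluster decision-factor statistic and its translation into six
    canonical ECG finding categories, diagnostic-accuracy metrics with
    bootstrap confidence intervals, and the clustered paired-proportions
    (Obuchowski) test for multi-reader studies.  A synthetic-data generator
    plants known reduced-ejection-fraction phenotype signatures so every
    pipeline stage has a ground-truth recovery target.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    randomForest,
    e1071,
    glmnet,
    nnet,
    uwot,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mclust
Config/testthat/edition: 3
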