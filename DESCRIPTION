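Package: cbda2
Title: Compressive Big Data Analytics by Subsampled Ensemble Prediction
Version: 0.2.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature mining and model mining for high-dimensional tabular
    biomedical data by compressive subsampling. Draws many small fixed-size
    subsamples of cases and features, fits a cross-validated stacking ensemble
    (SuperLearner-style, non-negative simplex weights) on each, ranks the
    subsample models by validation performance, and mines informative features
    from their appearance frequencies among the top-ranked models using a
    normal-approximation false-discovery cutoff and precision-recall AUC
    trajectories. Includes convergence diagnostics based on ensemble-weight
    distributions and Bray-Curtis dissimilarity, a nested-model overfitting
    test stage, generic data-wrangling filters, and the Null/Binomial
    synthetic benchmark generators with a Monte-Carlo Bayes-accuracy oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    ranger,
    xgboost,
    e1071,
    nnet,
    rpart,
    class,
    pracma,
    jsonlite,
    parallel
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
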