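Package: rbfrce
Title: Ensemble Feature Selection by Recursive Cluster Elimination with
    Random Bits Forests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Feature selection for high-dimensional small-sample data
    (e.g. microarray gene expression) using a bootstrap ensemble of
    trees built on randomized binary features, out-of-bag permutation
    importance, correlation-distance clustering of features, and
    recursive elimination of low-scoring feature clusters (RBF-RCE).
    Also provides the Fagin-style top-k intersection metric for
    measuring the stability of feature-selection results across
    perturbed training sets, combinatorial priors on selection overlap,
    a repeated stratified-holdout evaluation harness, and a synthetic
    data generator with planted informative features in correlated
    blocks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    randomForest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
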