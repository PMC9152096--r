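Package: rsvmcluster
Title: Random SVM Cluster Analysis of Functional Connectivity Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classifies two-group cohorts (e.g. autism spectrum disorder
    patients versus healthy controls) from resting-state functional
    connectivity features using a random support vector machine cluster:
    an ensemble of SVMs, each trained on a random subject subset and a
    random feature subspace, screened by validation accuracy and combined
    by majority vote. Candidate pathogenic brain regions are nominated by
    ranking edge appearance frequencies across high-accuracy ensemble
    members and aggregating them to region weights. Includes a
    planted-effect synthetic cohort generator (ROI time series with known
    group-differential Pearson correlations), parameter sweeps for
    ensemble size and subspace dimensionality, a baseline comparison
    harness with precision-recall curves, and cohort demographic summary
    tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
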