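Package: fcnet
Title: Functional Connectome Group Comparison and Behavior Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Whole-brain functional connectivity analysis for cohort studies:
    temporal preprocessing of region-of-interest BOLD time series, Fisher-z
    connectivity matrices, network-based statistic (NBS) group comparisons
    with a permutation max-component null, connectome predictive mapping
    (CPM) of behavioral scores with k-fold cross-validation and consensus
    networks, moderated regression of brain-behavior coupling with
    bias-corrected bootstrap confidence intervals, and a synthetic cohort
    generator with planted edge effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    signal,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
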