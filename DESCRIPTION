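Package: attbiomarker
Title: Two-Round Gene Selection and Attention-Based CNN Classification for Biomarker Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Workflow for discovering compact, discriminative gene subsets from
    labeled expression matrices. Implements per-study P-value prefiltering and
    cross-study common-gene matrix construction, two-round feature selection
    (Fisher criterion scoring with automated deflection-point subset sizing,
    then greedy minimum-redundancy maximum-relevance ranking on discretized
    expression), an attention-based one-dimensional convolutional network
    classifier with exact trainable-parameter accounting and ablation variants,
    stratified resampling with AUC/accuracy/F1/precision/recall reporting and
    the DeLong test for correlated AUCs, differential-expression intersection,
    degree-based hub ranking on interaction edge lists, and a synthetic
    multi-study expression simulator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    e1071,
    xgboost,
    optparse
Config/testthat/edition: 3
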