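Package: beoff
Title: Base-Editor Off-Target Activity Prediction from Guide-Target Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts Cas9-dependent off-target editing activity of adenine
    and cytosine base editors (ABE/CBE) as the off:on-target efficiency ratio
    of a gRNA/off-target pair. Implements gapped pairwise encoding of
    guide-target pairs, a fusion-embedding bidirectional LSTM regressor with
    attention pooling and inverse-prevalence-weighted loss, embedding-layer
    integrated-gradients attribution, hand-crafted-feature baseline models
    with sequential model-based hyperparameter search, quantification of
    pooled gRNA-target screen reads into editing efficiencies, specificity
    analytics (mutation-type and positional summaries, z-score maps,
    position-wise tests), and a fully seeded synthetic-data generator that
    emulates the screen so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo:
    Rcpp,
    RcppArmadillo
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    jsonlite,
    methods,
    Biostrings,
    S4Vectors,
    xgboost,
    nnet,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
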