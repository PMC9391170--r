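Package: kgdx
Title: Knowledge-Graph Embedded Clinical Indicators for Disease Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes clinical laboratory measurements against their reference
    ranges as a knowledge graph of indicator-value triples, learns translational
    embeddings (TransE, TransH, TransR) of the graph, and classifies patients
    with a self-attention plus convolutional network applied to the per-patient
    matrix of indicator-value relation vectors. Includes link-prediction
    evaluation (mean rank, Hit@10), SMOTE rebalancing, stratified
    cross-validation, attention-weight export for interpretability, and a
    synthetic cohort generator with a band-driven disease rule so the whole
    pipeline can be exercised end to end without access to hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
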