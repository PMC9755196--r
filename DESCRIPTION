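Package: hinmir
Title: Heterogeneous Network Representation Learning for Small
    Molecule-miRNA Association Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a three-node-type (small molecule, miRNA, disease)
    heterogeneous information network from association and similarity
    sub-networks, computes disease semantic similarity from MeSH-style
    tree numbers, learns node embeddings with two independently
    implemented heterogeneous-network representation learners (an
    adversarial one and a relation-typed random-walk one), merges the
    embeddings, forms labelled small molecule-miRNA pair vectors, and
    predicts and ranks candidate associations with a gradient-boosted
    tree classifier under stratified k-fold cross-validation. Includes a
    synthetic-network generator with planted low-rank association
    structure so the whole pipeline is testable without external
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    xgboost,
    e1071,
    rpart,
    class,
    jsonlite,
    yaml,
    rlang,
    optparse
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
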