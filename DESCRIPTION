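Package: divicp
Title: Multi-Level Single-Cell Integration by Divisive Iterative
    Clustering Projection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Batch-aware integration of single-cell expression data by
    divisive iterative clustering projection: self-supervised one-vs-rest
    L1-regularized logistic regression clustering on a batch-balanced
    training set of averaged cell profiles, doubling the cluster count
    each round by splitting clusters at batch-wise medians of assignment
    probability.  Cluster probability matrices from an ensemble of runs
    yield an integrated linear embedding, reference-to-query label
    transfer with k-nearest-neighbour voting and confidence scores, and
    probability-based cell-state inference.  Includes a negative-binomial
    multi-batch simulator with known ground truth and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    glmnet,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite
Config/testthat/edition: 3
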