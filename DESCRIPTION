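Package: lrsslmda
Title: Laplacian-Regularized Sparse Subspace Learning for miRNA-Disease
    Association Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts candidate miRNA-disease associations from a binary
    association matrix plus miRNA functional similarity and disease semantic
    similarity. Builds Gaussian interaction profile kernel similarities with
    a functional/semantic fallback, engineers statistical and
    graph-theoretical feature profiles for miRNAs and diseases, and fits a
    Laplacian-regularized sparse subspace learning model per side by
    alternating closed-form and multiplicative nonnegative updates. Includes
    the full cross-validation protocol (global and local leave-one-out,
    repeated k-fold) with rank-based ROC/AUC, a block-structured synthetic
    data generator for end-to-end validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'cli.R'
    'evaluation.R'
    'features.R'
    'io.R'
    'laplacian.R'
    'lrsslmda-package.R'
    'optimizer.R'
    'pipeline.R'
    'predict.R'
    'similarity.R'
    'synthetic.R'
    'utils.R'
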