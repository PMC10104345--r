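Package: grace
Title: Graph-Autoencoder Single-Cell Clustering via Ensemble Similarity Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Clusters single-cell RNA-seq expression profiles by building an
    ensemble cell-to-cell co-association similarity network from repeated
    clustering over random subsets of high-variance feature genes, embedding
    cells with a two-layer graph convolutional autoencoder trained against the
    ensemble similarity graph, and deriving cluster labels and an estimate of
    the number of cell types via the elbow method and k-means. Includes CPM and
    log2 normalization, external clustering validation metrics (adjusted Rand
    index, normalized mutual information, pairwise Jaccard index, purity), a
    cluster-number estimation-error summary, and a negative-binomial synthetic
    single-cell count simulator with planted cell types for testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rtsne,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse,
    rhdf5
Config/testthat/edition: 3
RoxygenNote: 7.3.3
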