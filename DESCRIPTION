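Package: scLineageNet
Title: Supervised Cell-Type Annotation for scRNA-Seq with
    Correlation-Guided Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Supervised annotation of single-cell RNA-seq data against a
    labelled reference. Per-type mean expression profiles and their Pearson
    correlation matrix decide between two classifiers: a multi-class
    feed-forward neural network when cell types are well separated, and a
    cell-lineage hierarchical classifier when highly correlated types are
    present. The hierarchical route combines marker-gene sensitivity
    pre-assignment with a complete-linkage lineage tree whose bifurcations
    carry binary neural networks trained on moderated-t selected features.
    Every test cell receives a concrete training-set label. Includes a
    negative-binomial simulator with controllable cell-type correlation
    structure, planted exclusive markers and dropout, plus accuracy and
    adjusted-Rand-index scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    limma,
    jsonlite,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
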