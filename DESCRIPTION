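Package: ProbePanels
Title: Gene Panel Selection, Evaluation and Probe Design for Targeted
    Spatial Transcriptomics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end workflow for designing targeted spatial
    transcriptomics experiments from a dissociated single-cell reference:
    combinatorial decision-tree based gene panel selection that jointly
    optimises cell type identification and variation recovery, a
    twelve-metric panel evaluation suite (clustering similarity via
    normalized mutual information, neighborhood similarity, classification
    accuracy, marker correlation, gene redundancy and expression
    constraints), spatial-data metrics (Moran's I spatial variation and
    cell-cell interaction recovery via linear node-centric expression
    models), and a padlock/encoding probe design stage that filters
    candidate oligos by sequence properties, cross-hybridization and
    off-target binding and assembles ready-to-order probe sequences.
    Includes a synthetic data module that generates negative-binomial
    count matrices with planted cell types and markers, spatial datasets
    with planted autocorrelation and interaction effects, and synthetic
    transcriptomes with multi-isoform genes and paralog pairs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    GenomicRanges,
    IRanges,
    Biostrings,
    rtracklayer,
    igraph,
    rpart,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics,
    ape,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Transcriptomics, SingleCell, Spatial, FeatureSelection,
    Classification, Software
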