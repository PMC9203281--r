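Package: cerebroid
Title: Regional Identity Analysis for Cerebral Organoid Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assigns regional (cortical versus non-cortical) identity to
    cerebral organoid transcriptomes across derivation protocols. Implements
    atlas-based regional marker gene derivation with a confound filter,
    RPKM/equal-sum/quantile normalization, empirical-Bayes batch adjustment
    and correspondence analysis for joint embedding of organoid and fetal
    brain atlas samples, negative-binomial Wald differential expression with
    gene-set enrichment (Fisher and permutation GSEA) and a Venn z-score
    summary, a single-cell pipeline (QC, median normalization, highly
    variable genes, PCA, plain and batch-balanced kNN graphs, Louvain
    clustering, simulated-doublet scoring, overestimated-variance t-tests,
    cross-dataset cluster annotation), and deterministic steady-state RNA
    velocity on spliced/unspliced layers. Ships a synthetic-data generator
    that plants regional markers, protocol mixtures, batch shifts, cell
    types, doublets and kinetic regimes with a ground-truth ledger.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    matrixStats,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    igraph,
    limma,
    jsonlite,
    yaml,
    mclust
Suggests:
    testthat (>= 3.0.0),
    sva,
    DESeq2,
    pROC,
    cluster,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'bulk-normalize.R'
    'de.R'
    'enrichment.R'
    'integration.R'
    'io.R'
    'region-markers.R'
    'sc-de.R'
    'sc-graph.R'
    'sc-preprocess.R'
    'sc-doublets.R'
    'synth-atlas.R'
    'synth-singlecell.R'
    'velocity.R'
    'workflows.R'
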