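Package: quadloop
Title: Integrative Analysis of DNA G-Quadruplex Landscapes and Chromatin Architecture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the integrative analysis of DNA G-quadruplex (G4) profiling
    data across cell-state transitions: strand-aware scanning of putative
    quadruplex-forming sequences (PQS) with a four-class structural subtype
    taxonomy (canonical, long-loop, bulged, two-quartet), G4 peak-landscape
    comparisons (set sharing, binned signal correlation, genomic feature
    distribution, transcription-factor co-binding), promoter-G4 target-gene
    classification chained through differential expression and ligand
    perturbation, and G4-anchored chromatin-loop analytics on binned contact
    matrices (anchor classification, observed/expected normalisation, aggregate
    peak analysis, distance-stratified differential interactions, expression
    stratification by loop class). A seeded synthetic-data generator emulates
    the statistical structure of the sequencing-derived inputs and emits a
    machine-readable truth table for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    edgeR
Config/testthat/edition: 3
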