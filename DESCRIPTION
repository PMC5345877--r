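Package: tfgate
Title: Imputing Cell-Specific Transcription Factor Binding with Gated
    Convolutional Embedding Networks
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts cell-line-specific transcription factor (TF) binding
    from DNA sequence with a multi-task convolutional network in which
    learned TF and cell-line embeddings compute per-filter gates that
    modulate motif detectors.  Includes the full surrounding workflow:
    ChIP-seq/DNase-seq peak ingestion, dinucleotide-preserving shuffled
    negatives and union-DHS matched negatives, combination-level data
    partitioning for imputation benchmarks, AdaDelta training with dual
    validation checkpointing, ROC/recall-at-FDR evaluation with
    shuffled-label controls, variant (SNP) allele-effect scoring, an
    enhancer-activity PCA signature, embedding clustering, and a synthetic
    planted-motif data generator so that every stage is testable without
    any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
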