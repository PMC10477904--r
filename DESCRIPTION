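Package: lncfunnel
Title: Prioritization of Disease-Associated Variants in Long Non-Coding
    RNAs by Structure Disruption Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for prioritizing GWAS variants that fall
    inside long non-coding RNAs. Variant tables are intersected with
    transcript annotations (BED12/GTF), exonic hits are mapped onto mature
    spliced transcripts, and the structural consequence of each allele
    substitution is scored with equilibrium base-pair probabilities from a
    partition-function model, calibrated against an empirical resampling
    null. Companion quantification tools cover qPCR relative expression
    (2^-ddCt), nucleus/whole-cell fractionation ratios, RNA-seq count
    filtering with upper-quartile normalization, hypergeometric gene-set
    overrepresentation, and RIP-qPCR percent-of-input enrichment. Seeded
    generators emulate every input with ground-truth labels so the whole
    pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    withr,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
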