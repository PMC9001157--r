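Package: refkit
Title: Build and Evaluate Multi-Locus Chloroplast Reference Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constructing and evaluating multi-locus DNA barcoding
    reference databases from targeted-capture sequencing of chloroplast gene
    regions. Provides hybridization-capture probe panel design (greedy identity
    clustering and 120-mer probe tiling), consensus calling from quality-filtered
    pileups with read-depth masking, gene-region annotation by local alignment,
    gene-recovery accounting, leave-one-out taxonomic assignment, and Kimura
    two-parameter (K2P) distance analyses per gene region and under iterative
    gene concatenation, including UPGMA dendrograms. A synthetic-data generator
    simulates rank-structured taxonomies, sequences evolving under a K2P
    substitution model with per-gene rate variation, gene dropout, and
    quality-labelled pileups, so every pipeline stage can be exercised and
    validated end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    seqinr,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    Biostrings,
    phangorn,
    knitr,
    rmarkdown
Config/testthat/edition: 3
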