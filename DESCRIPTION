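Package: sspminer
Title: Discovery and Classification of Small Secreted Peptides in Plant Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy toolkit for genome-wide discovery of small secreted
    peptides (SSPs) in plants. Implements the four-stage SSP identification
    cascade (size gate, N-terminal signal peptide, transmembrane exclusion,
    ER-retention exclusion) with pluggable SignalP-5.0/TMHMM-2.0 output
    parsers or built-in heuristic predictors; rule- and motif-based peptide
    family classification with cysteine-rich peptide (CRP) detection and
    novel-family discovery by cysteine-spacing signatures; six-frame mining
    of unannotated small open reading frames from non-coding genomic
    sequence; CEP domain architecture analysis; drought-stress differential
    expression filtering, qPCR relative expression, and stress-physiology
    calculators (RWC, REC, MDA) with one-way ANOVA group comparison.
    Includes synthetic-data generators with fully known ground truth so
    every pipeline stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
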