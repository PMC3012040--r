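Package: methclones
Title: Clone-Level Analysis of Bisulfite-Sequenced DNA Methylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing and exploratory analysis of single-gene bisulfite
    sequencing experiments. Reads reference and clone sequences (FASTA or
    GFF3 with an embedded FASTA section), resolves clone orientation by
    global alignment under a bisulfite-tolerant substitution scheme,
    computes per-clone quality control (bisulfite conversion ratio and
    A/G/T-restricted identity rate), extracts a clone-by-CpG ternary
    methylation matrix, and provides summary statistics, neighbouring and
    distant co-occurrence, per-site Fisher exact tests, Mann-Whitney set
    tests, Hamming-distance biclustering, correspondence analysis, and
    lollipop, matrix, biplot and heatmap displays. Includes a seeded
    simulator of bisulfite clones with known ground truth and a pipeline
    runner with a command-line launcher.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    patchwork,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
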