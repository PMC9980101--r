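Package: hapchain
Title: Chromosome-Scale Haplotype Phasing of Blunt Assembly Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extends partial haplotype phasing in a blunt diploid assembly
    graph to chromosome scale. Proximity-ligation alignments (Hi-C or
    Pore-C) are reduced to a weighted contact graph over segments, and a
    sampled greedy max-cut optimizer with consistency-based bubble merging
    assigns a haplotype orientation to every bubble; alternatively,
    parent-unique k-mers phase bubbles by majority vote. Phased bubbles are
    chained through strict diploid topology and unzipped into two haplotype
    paths and FASTA sequences. Includes MinHash-based homology search for
    bubble detection, a contact-level QC module (contacts per read, signal
    ratio against a diploid truth), and a seeded synthetic-fixture
    generator for closed-loop testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    withr,
    Rcpp,
    Biostrings,
    Rsamtools,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
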