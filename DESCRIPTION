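Package: pacfinder
Title: Poly(A) Site Cluster Calling and Alternative Polyadenylation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Genome-wide identification and analysis of mRNA cleavage and
    polyadenylation sites from 3'-end evidence in sequencing reads, tuned for
    GC-rich genomes such as the green alga Chlamydomonas reinhardtii. Detects
    untrimmed poly(A)/poly(T) tails under EST- or short-read-specific rule
    sets, places trimmed read bodies on a reference genome, filters
    internal-priming artifacts arising from genomic adenosine runs, and
    merges cleavage microheterogeneity into poly(A) site clusters (PACs)
    with a span-constrained minimum-variance clustering. Downstream modules
    assign PACs to genic regions with a 3'-UTR extension rule, scan flanking
    sequences for polyadenylation signals (e.g. UGUAA) under three k-mer
    counting modes scored against Markov-chain backgrounds, classify
    alternative polyadenylation (APA) site categories, and quantify the
    interplay between intronic polyadenylation and splicing. A synthetic-data
    generator produces GC-biased genomes, annotations, and tailed reads with
    planted ground truth so that every stage is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    rtracklayer,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
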