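Package: pcpatools
Title: Poly(A)-Site Calling, PAS Motif Discovery, and Codon Usage Statistics
    for Premature Cleavage and Polyadenylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for quantifying premature cleavage and
    polyadenylation (PCPA) from 3'-end sequencing data. Processes raw
    poly(A)-primed reads (poly(A)-tail trimming, internal-priming and
    untemplated-A filters), clusters mapped read 3'-ends into poly(A)-site
    peaks with summit calling, classifies sites against gene annotation
    (3'UTR with a 1-kb extension, ORF, intron, 5'UTR, intergenic), discovers
    enriched polyadenylation-signal hexamers against a dinucleotide-shuffle
    null, builds position-specific scoring matrices for PAS scoring, and
    computes codon usage indices (RSCA, CBI, CAI) together with codon and
    codon-pair enrichment statistics around termination sites (NCUF, NCPF,
    RCUF). A seed-deterministic synthetic-data generator emulates genomes
    with tunable wobble-position G/C bias, implanted PAS signals, dispersed
    cleavage sites, and internal-priming artifacts, so the whole pipeline is
    testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
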