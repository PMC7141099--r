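Package: nlrsweep
Title: Genome-Wide Identification of NBS-LRR Disease Resistance Gene Candidates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies candidate NBS-LRR (NLR) plant disease resistance genes
    directly from a genome assembly, without relying on existing gene
    annotations. A two-pass translated homology search locates the conserved
    NB-ARC domain in all six reading frames, merges and chains hits across
    small introns, and applies a domain-completeness filter; peptides from
    first-pass candidates are multiply aligned to build species- and
    class-specific position-specific scoring matrices that drive a second,
    more sensitive pass. Candidate loci plus 10 kb of flanking sequence are
    annotated for ORFs, leucine-rich repeats, coiled-coil, TIR and RPW8
    domains, classified into the CNL/TNL/RNL/NL classes, filtered on LRR
    presence, and exported as BED and GFF3 for manual curation in a genome
    browser. Includes a synthetic-genome simulator with truth annotations and
    an evaluation module for sensitivity/precision benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
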