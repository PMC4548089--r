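Package: plastcomp
Title: Comparative Mutation Analysis of Chloroplast Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pairwise (and three-way) comparison of annotated plastomes:
    detection of the quadripartite structure (LSC/IRb/SSC/IRa), microsatellite
    (SSR) scanning with mono- and di-nucleotide thresholds, calling and
    classification of mutation events (SNPs as transition/transversion and
    synonymous/non-synonymous, indels as SSR-slippage or non-SSR, short
    micro-inversions), and sliding-window nucleotide diversity (Pi) with
    divergence-hotspot calling. Includes a synthetic plastome-pair generator
    that emits a ground-truth mutation ledger so every pipeline stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    seqinr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
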