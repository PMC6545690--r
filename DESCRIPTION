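Package: targetec
Title: Targeted Error Correction of Illumina Reads Near Repetitive Homopolymers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Targeted correction of paired-end Illumina sequencing reads that
    overlap highly repetitive low-complexity patterns such as poly(A/T)
    homopolymers. Read pairs containing such a pattern are extracted, clustered
    into per-locus groups by combining overlap-alignment similarity of both
    mates with Louvain community detection stabilised by cross-run core
    consensus, and each cluster is corrected independently: a small-k de Bruijn
    graph is built and cleaned (two-Poisson mixture coverage cutoff fitted by
    expectation-maximisation, conservative multi-round tip and bubble removal)
    and reads are realigned to the cleaned graph by seed-and-extend search.
    Includes a paired-end read simulator with planted homopolymer hotspots and
    evaluation utilities (correction gain against simulated truth, assembly
    NGA50 summary statistics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
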