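Package: amplitree
Title: In Silico Evaluation of Universal PCR Primers and eDNA
    Metabarcoding Read Processing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing "universal" (taxon-wide) PCR primer pairs
    against a local taxonomy-annotated reference database and for processing
    multiplexed environmental-DNA (eDNA) amplicon sequencing runs. The
    in-silico PCR component predicts amplicons for degenerate primer pairs,
    aligns them, builds taxonomically annotated Neighbor-Joining trees and
    reports per-rank resolution metrics. The read-processing component
    demultiplexes indexed paired-end reads, identifies and trims primers,
    applies length and abundance filters, merges read pairs into quality-
    resolved consensus sequences, dereplicates them and assigns species by
    best-hit identity against the reference database, yielding per-sample
    presence/absence matrices and exact association tests. A simulation
    module generates taxonomy-structured reference databases and complete
    synthetic sequencing runs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    grDevices,
    IRanges,
    jsonlite,
    Rcpp,
    S4Vectors,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
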