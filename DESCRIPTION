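Package: mircam
Title: Small RNA Sequencing Analysis for Plant miRNA Discovery,
    Quantification and Target Prediction
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, deterministic re-implementation of a plant
    small-RNA-seq miRNA discovery analysis: 3' adapter clipping, quality
    and length filtering, read collapsing to unique sequence tags, exact
    genome anchoring, known-miRNA matching against a mature reference set,
    mismatch-tolerant homology search for novel candidates, precursor
    window extraction with minimum-free-energy hairpin folding (an
    embedded nearest-neighbor dynamic program), miRNA/miRNA* duplex
    calling under MFE, stem-loop-length and complementarity criteria,
    per-tissue expression tables with signed fold changes, and
    complementarity-based target prediction in coding sequences. A
    synthetic-data generator emulates adapter-bearing sequencing
    libraries with implanted hairpin loci and known ground truth so the
    whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
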