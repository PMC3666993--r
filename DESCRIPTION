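Package: peakdose
Title: Comparing ChIP-seq Binding Profiles Across Transcription Factor Doses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing the genome-wide binding profiles of a
    transcription factor assayed at different protein doses, as in
    endogenous-versus-overexpressed ChIP-seq designs. Implements peak calling
    against a negative-binomial background model conditioned on local GC
    content, empirical FDR curves, control-peak subtraction, rank-cutoff
    peak-set concordance grids, E-box (CANNTG) occupancy and variant-preference
    analyses stratified by chromatin accessibility, and discriminative de novo
    motif discovery with ZOOPS expectation-maximization refinement of position
    weight matrices. A synthetic-data generator produces genomes, binding
    sites, and read sets with the statistical structure the analysis assumes,
    so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    graphics,
    BiocGenerics,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
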