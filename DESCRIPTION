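Package: dsbscape
Title: Genome-Wide Analysis of Endogenous DNA Double-Strand-Break Hot Spots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for the analysis of endogenous DNA
    double-strand-break (DSB) site maps and rDNA-contacting (4C) site maps:
    repeat filtering and replicate intersection of counted site sets, windowed
    hot-spot calling at a top-percentile threshold, quartile stratification,
    RPKM-normalised mean coverage tracks, assignment of sites to genes and
    genomic categories with enrichment statistics, hypergeometric and
    Monte-Carlo gene-list overlap tests, Mann-Whitney and Monte-Carlo
    expression-distribution comparisons, CAGE-based bidirectional promoter
    classification, and anchored z-score signal metaprofiles. A seeded
    synthetic mini-genome generator emulates the statistical structure the
    analysis assumes, so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
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
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
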