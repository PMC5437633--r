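Package: ssrdecay
Title: Imperfect Microsatellite Detection, Conservation Mapping and
    Decay-Rate Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects perfect and imperfect microsatellites (1-6 nt motifs) in
    genome and CDS sequences with a seed-and-extend scanner, canonicalizes
    motifs under cyclic rotation and reverse complementation, and relates
    motif imperfection to repeat length with canonical ordination, PERMANOVA,
    pairwise correlations and regression. Maps locus conservation between
    progenitor and derived (sub)genomes using hard-masked, flank-based locus
    libraries and a reciprocal seed-extend homology search, converts per-class
    conserved fractions into exponential decay rates over a stated divergence
    time, and contrasts relative decay and relative abundance across genomes.
    A synthetic-genome simulator with complete ground truth (planted repeats,
    transposable-element intervals, progenitor-to-tetraploid evolution with
    known per-class loss rates) makes every stage testable without external
    assemblies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    GenomicRanges,
    IRanges,
    rtracklayer,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
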