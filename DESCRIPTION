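Package: satseeker
Title: Satellite Monomer Discovery and Optical-Map Repeat Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for characterizing centromeric satellite DNA from
    long reads, genome assemblies and optical (Bionano-style) maps.
    Detects tandem repeats with a seed-and-extend wraparound
    dynamic-programming aligner, collapses harmonic periods to a base
    monomer, mines the enriched monomer and builds its strand- and
    rotation-invariant consensus, annotates satellite arrays across
    assembly scaffolds with gap and scaffold-end context, computes
    assembly statistics under an N-run contig convention, performs
    in silico nicking digestion, detects periodic label spacing in
    optical-map molecules, calls higher-order-repeat regions on
    consensus maps, and ranks nicking enzymes for targeted physical-map
    characterization of centromeres. Ships deterministic seeded
    simulators for satellite reads, higher-order-repeat arrays, toy
    assemblies and noisy label molecules, plus a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    S4Vectors,
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
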