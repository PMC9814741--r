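Package: defectometer
Title: Data-Driven Detection of Molecular Motifs and Defects in
    Self-Assembled Aggregates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes SOAP (Smooth Overlap of Atomic Positions) descriptors
    for the monomer centers of coarse-grained self-assembly trajectories,
    detects molecular motifs (ordered, defect, adsorbed states) by
    density-based mode-seeking clustering of the principal-component
    projections, quantifies per-monomer state populations and transition
    probabilities, and classifies whole assemblies through the metric
    induced by the averaged-SOAP linear kernel.  Ships synthetic generators
    for fibers, planar lattices, micellar shells and droplets with planted
    ground-truth states, so the full workflow is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
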