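Package: xirep
Title: Quantitative Image Analysis of Inactive X Chromosome Replication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale implementation of the image-derived quantifications
    used to study synchronous replication-origin firing on the inactive X
    chromosome (Xi): triangle-threshold segmentation of nuclei and the
    H3K27me3-marked Xi territory, 3D replication nano-foci picking by
    plateau-aware local maxima with prominence-based separation, proximity
    ligation assay (PLA) spot counting, EdU/PCNA progression ratios, RPA
    coefficient-of-variation time courses, pre-replication-complex loading
    coefficients, DNA-halo morphometry with FISH line profiles, live-imaging
    replication-pattern timing, a replication fork-speed arithmetic model, and
    ChIP peak density per chromosome. A synthetic multichannel microscopy
    generator with condition presets and ground truth stands in for raw image
    data so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
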