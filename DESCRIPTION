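Package: openptm
Title: Downstream Analysis of Open-Search Delta-Mass Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the downstream analysis of open-search (wide precursor
    tolerance) proteomics results: recalibration and peak modelling of the
    delta-mass distribution, target-decoy FDR control at global, local and
    peak levels, annotation of mass shifts against a modification catalog
    including composite (multi-modification plus C13 isotope) decomposition,
    residue- and sequence-quintile specificity profiling with artefact
    classification, aggregation of modified peptides into protein sites,
    standardized spectral-count quantitation with protein-level
    normalization, and cohesiveness-based correlation-network clustering of
    site responses across treatment groups. A seeded synthetic-data
    generator emulates the statistical structure of an open-search PSM
    table so that every stage is testable without raw mass spectrometry
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    igraph,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
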