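Package: oligofoot
Title: Size-Resolved MNase Footprint Mapping and Occupancy Analysis for
    Chromatinized Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for micrococcal-nuclease (MNase) protection
    data from bacteria expressing archaeal histones. Maps size-resolved
    protection footprints left by oligomeric histone complexes (tetramer
    60 bp core extended in 30 bp dimer steps), computes empty-vector
    normalized occupancy tracks, models sequence preferences of occupancy
    with k-mer LASSO regression, and links promoter occupancy to
    differential gene expression and transcriptome-compendium similarity.
    Includes a synthetic-data generator that emulates oligomeric assembly,
    AT-biased MNase digestion and occupancy-coupled expression so that the
    full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
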