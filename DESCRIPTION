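Package: anthoflux
Title: Isotope Flux, Stage Profiles, and Correlation Networks for Flower Anthesis Multi-Omics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for multi-omics studies of flower development
    across anthesis. Quantifies metabolic fluxes from radiolabel (14C)
    partitioning experiments with isotopic-dilution accounting, corrects
    measured mass-isotopologue distributions for natural isotope abundance and
    quantifies 13C enrichment, summarises stage-resolved metabolite profiles
    (normalisation, log2 stage means, relative abundances, pairwise t-tests
    with compact letter displays), builds thresholded Pearson correlation
    networks with betweenness centrality, and runs an RNA-seq count funnel
    (low-count filtering, log-CPM, smooth developmental-trend filtering,
    stage contrasts, k-means profile clustering). A seeded synthetic-data
    generator emulates the experimental designs so every stage of the
    pipeline is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
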