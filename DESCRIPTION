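Package: homscaffold
Title: Homological Scaffolds of Weighted Functional Connectivity Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Topological data analysis of weighted, signed, fully connected
    networks such as resting-state functional connectivity matrices. Builds
    the weight rank clique filtration, computes one-dimensional persistent
    homology with representative cycles, and summarises the result as the
    frequency and persistence homological scaffolds together with the nodal
    persistence scaffold strength (PSS). Also provides the standard binary
    and weighted graph centralities (degree, betweenness, local efficiency,
    strength, participation coefficient), proportional thresholding across a
    density grid, Louvain community detection, and an end-to-end comparison
    workflow relating PSS to the standard metrics, plus seeded synthetic
    generators for block-correlated functional-connectivity studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    tibble,
    dplyr,
    purrr,
    rlang,
    withr,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
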