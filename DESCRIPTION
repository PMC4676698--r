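Package: smlmtools
Title: Molecular Interaction and Cluster Analysis for Single-Molecule
    Localization Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of molecular position tables produced by
    single-molecule localization microscopes (PALM/STORM/GSD). Implements
    nearest-neighbour spatial association analysis with a precision-derived
    colocalization distance criterion and Monte-Carlo randomized controls,
    cross-channel pair-correlation (RDF) and Ripley K/H statistics with
    cluster-radius estimators, density-based (DBSCAN) and reachability-based
    (OPTICS) cluster segmentation including hierarchical reachability-plot
    segmentation, plus synthetic scene generators that emulate stochastic
    super-resolution acquisition and its over- and under-sampling artefacts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    tiff,
    stats,
    graphics,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
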