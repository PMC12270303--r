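Package: colonytda
Title: Topological Classification of Stem Cell Colony Point Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies human induced pluripotent stem cell colonies by
    differentiation treatment from the spatial layout of their cells alone.
    Cell-centroid point clouds are summarised by Vietoris-Rips persistent
    homology in dimensions 0 and 1, vectorised as sampled persistence
    landscape matrices, and classified with a small feedforward neural
    network trained timepoint by timepoint. Includes a synthetic colony
    generator with class-specific spatial motifs (boundary fringe, rosette
    voids, enlarged footprint), randomized-label controls, per-class
    precision/recall/F1 reports, cross-timepoint accuracy grids and the
    time-differential accuracy metric.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
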