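Package: autocmap
Title: Semantic Connectivity Maps from Auto-Contractive Map Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers association networks from mixed-type cohort tables with
    the Auto-Contractive Map (Auto-CM), an unsupervised three-layer neural
    system whose weights grow monotonically toward a contraction constant as
    a function of the co-activation of variables across records. Provides
    binary/min-max encoding of mixed binary and continuous variables,
    Auto-CM training, translation of learned weights into strengths of
    association (SA), minimum-spanning-tree filtering into a semantic
    connectivity map with hub detection, a seeded Gaussian-copula generator
    of synthetic mother-placenta-neonate methylation/exposure cohorts, and
    standard-curve quantification for methylation-sensitive high-resolution
    melting (MS-HRM) assays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
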