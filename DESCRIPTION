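Package: mihsim
Title: Individual-Based Eco-Evolutionary Simulations of Species-Energy
    Relationships
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: An individual-based eco-evolutionary simulator for testing the
    more-individuals hypothesis and related species-energy theory. Organisms
    carry 64-bit binary genomes whose fit to a three-channel raster
    environment determines how per-cell energy is shared; breeding is gated
    by genetic compatibility, and species are delimited under the biological
    species concept as reproductively isolated clusters. The package
    generates the study environments (static spatial-heterogeneity noise
    rasters, block-expanded variants, and dynamic moving-lights sequences),
    runs configurable-scale versions of the species-richness, abundance,
    extinction-risk, speciation-rate and evenness experiments, and provides
    the statistical layer (segmented linear models with breakpoint standard
    errors, nested-model F tests, and log-linear extinction-risk models).
License: GPL (>= 3)
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    png,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
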