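Package: seascapeCI
Title: Seascape-Stratified Control-Impact Assessment of Marine Reserves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing marine reserve effectiveness while
    controlling for seascape heterogeneity. Simulates lagoon patch-reef
    seascapes and fish/coral survey data, quantifies patch configuration,
    composition and structure metrics from habitat and bathymetry rasters,
    relates community variation to seascape metrics via canonical
    correspondence analysis with forward model selection and permutation
    tests, classifies sites into seascape groups by hierarchical
    clustering, and contrasts pooled versus seascape-stratified
    Control-Impact comparisons, including Bray-Curtis/ANOSIM community
    tests and power experiments that quantify how seascape variation can
    mask reserve effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    stats,
    utils,
    MASS,
    mclust,
    igraph,
    generics
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
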