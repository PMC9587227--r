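Package: pgdplan
Title: Spatial Conservation Prioritization with Proxies of Genetic Differentiation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds spatially explicit proxies of genetic differentiation (PGD)
    by classifying a climate stack into Holdridge life zones and subdividing
    them with historical-isolation cartography (biogeographic provinces,
    watersheds, edaphology), crosses them with binarized species distribution
    models into conservation-feature stacks, ranks the landscape with the
    greedy core-area zonation (CAZ) removal rule under habitat-condition
    layers and IUCN threat weights, and evaluates representation of taxa and
    PGD under alternative scenarios with performance curves, overlay
    statistics, and genetic-cluster cross-validation. Includes a seeded
    synthetic-landscape generator so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
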