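Package: odhotspot
Title: Multi-Phase Geospatial Cluster Analysis of Overdose Incident Rates
Version: 0.1.0
Authors@R: person("O.", "Devlin", email = "odevlin@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for hot-spot epidemiology of drug-overdose
    incidents at the areal-unit (census block group) level. Cleans
    EMS-style incident records under explicit exclusion rules, constructs
    incident rates per 1,000 adult population, classifies rates with exact
    Jenks natural-breaks optimization, tests global clustering with an
    edge-corrected Ripley's K function against a Monte-Carlo complete
    spatial randomness envelope, detects local hot and cold spots with
    local Moran's I (LISA) under conditional permutation inference on
    queen-contiguity weights, and relates hot spots to sociodemographic
    covariates and health-facility access through conditional cluster
    tables. Includes a synthetic-city generator with planted hot blocks
    and record contamination so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
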