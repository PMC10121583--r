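Package: reefshield
Title: Carbonate Budgets, Coral-Restoration Projections, and Storm-Driven
    Flooding Assessment for Reef-Lined Coasts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Census-based coral-reef carbonate budgets (gross carbonate
    production with rugosity correction, parrotfish/urchin/endolithic
    bioerosion, net production, framework density and reef-accretion
    potential), conversion of repeated buoyant-weight and caliper
    measurements of assay corals into calcification and extension rates, a
    decadal cohort model of Acropora palmata outplanting on the reef crest,
    keep-pace assessment of reef accretion against sea-level-rise scenarios,
    and post-processing of externally computed shoreline total-water-level
    tables under restoration-adjusted sea levels. Includes a synthetic-data
    generator that emulates the underlying survey designs so every pipeline
    stage is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
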