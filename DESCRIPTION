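Package: teamflux
Title: Temporal Expression-Based Analysis of Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dynamic flux balance analysis constrained by time-series gene
    expression. At each time step the flux distribution minimally inconsistent
    with expression data is found by a two-stage linear program with
    GIMME-style reaction penalties, using global or gene-specific expression
    thresholds derived from a reference compendium; the resulting exchange
    fluxes update extracellular metabolite pools and biomass for the next
    step. Includes a plain dFBA baseline, a threshold-percentile sensitivity
    sweep with secretion-zone classification, an inconsistency score for
    comparing thresholding strategies, and a self-contained synthetic-data
    generator (toy overflow-capable metabolic model, expression time series,
    expression compendium, growth curve, media).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
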