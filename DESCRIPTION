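Package: resghg
Title: Reservoir Greenhouse-Gas Emission Assessment and Low-Carbon Dam Planning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Desk-scale toolkit for planning low-carbon reservoirs. Estimates
    biogenic greenhouse-gas emissions from reservoirs via climate-zone Tier 1
    emission factors or a configurable pathway-structured empirical model,
    converts gross to net anthropogenic emissions, recalibrates
    country-specific emission factors with bootstrap uncertainty, delineates
    reservoirs and catchments on gridded terrain (D8 routing, Pfafstetter
    sub-basin compilation, full-supply-level flooding), explains emission
    drivers with gradient-boosted surrogate models and additive breakdown
    attributions, and selects dam portfolios on tree-structured river networks
    with an epsilon-approximate multiobjective dynamic program. A synthetic
    landscape and fleet generator with a known ground-truth emission law makes
    every component testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
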