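Package: oceanch4
Title: Ocean Methane Disequilibrium Mapping and Air-Sea Flux Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end pipeline for estimating oceanic methane emissions
    from sparse shipboard observations. Converts dissolved CH4 measurements to
    methane disequilibrium (dCH4) using solubility and moist-air partial
    pressure, bins them into a monthly gridded climatology, trains ensembles of
    neural-network and regression-forest models to map dCH4 from environmental
    predictors, propagates wind, sea-ice and gas-transfer-velocity uncertainty
    into diffusive air-sea fluxes by Monte Carlo, models bubble-mediated
    (ebullitive) transfer from seafloor seeps with a two-gas bubble dissolution
    model, and analyses the drivers of the dCH4 distribution. Ships a synthetic
    world generator that emulates the statistical structure of the underlying
    observational database for testing and demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nnet,
    randomForest,
    deSolve,
    geosphere,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
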