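Package: oakmap
Title: Constrained Ensemble Species Distribution Modelling of Oak Woodland
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An ensemble species-distribution modelling pipeline for mapping
    oak-dominated woodland from stand inventories and biophysical site rasters.
    Balanced presence/pseudo-absence pixel tables are fitted with four learners
    (logistic regression, gradient-boosted trees, random forest, neural
    network) under repeated 50/50 cross-validation over 15 absence replicates,
    scored and weighted by the true skill statistic, and combined into a
    probability raster. The raster is masked to broadleaved woodland, ranked,
    and filtered by a regional stocked-area target and by a 10 m
    elevation-class histogram; predictions are validated against independent
    site locations with exact binomial statistics and Clopper-Pearson
    intervals. A seeded synthetic landscape generator supplies covariate
    stacks, stand tessellations, inventory-style summaries and held-out
    validation sites so the whole pipeline is testable without confidential
    forest data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    nnet,
    ranger,
    xgboost
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
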