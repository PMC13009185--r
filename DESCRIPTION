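Package: seepscape
Title: Seep-Scale Habitat Suitability Modelling and Isotope Analysis for Cold-Water Corals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for site-scale analysis of cold-water corals at methane seeps:
    simulation of a synthetic seep mound with known ground truth, derivation of
    bathymetry-based terrain predictors (slope, northness/eastness, bathymetric
    position index, vector ruggedness, curvature) and Euclidean distance-to-feature
    layers, fishnet-based active/transition habitat classification of occurrence
    points, presence-background ensemble habitat suitability modelling (random
    forest and gradient boosting) under spatial-block cross-validation with
    permutation variable importance and TSS-weighted ensembling, and stable-isotope
    computations for 13C-methane labelling incubations (group summaries, Welch's t,
    one-way ANOVA, enrichment classification).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    randomForest,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
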