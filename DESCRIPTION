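Package: afpop
Title: Population-of-Models Simulation of Atrial Fibrillation Inducibility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An in-silico pharmacology pipeline for atrial arrhythmia studies:
    Latin-hypercube generation and biomarker-based calibration of a population
    of human atrial myocyte models with chronic-AF remodeling, 2D monodomain
    tissue simulation with an S1-S2 cross-field induction protocol under
    pore-block drug models, Hilbert-phase rotor detection and tracking for
    inducibility labeling, and random-forest classification of inducibility
    from ionic-profile features with interpretable decision-path (sunburst)
    extraction. Ships a fast two-variable surrogate myocyte model and
    synthetic-data generators so every stage can be exercised at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    lhs,
    randomForest,
    rpart,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
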