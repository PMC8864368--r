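Package: traitdisp
Title: Trait Dispersion Null Models and Driver Selection for Eelgrass Epifauna
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the dispersion of functional traits in
    site-level communities of eelgrass-associated peracarid crustaceans.
    Computes Gower distances over mixed-type trait tables (continuous,
    ordered, categorical and binary traits with missing values), mean
    pairwise distance (MPD) and mean nearest taxon distance (MNTD) for
    site assemblages, and standard effect sizes (SES) against permutation
    null models (independent swap and tip shuffle) scoped to global or
    ocean-level species pools. Includes an a priori regression model
    registry with AICc ranking, composite-model construction with
    variance-inflation screening and backward elimination, and a
    synthetic-data generator that assembles communities under tunable
    environmental filtering and limiting similarity along latitudinal
    gradients, so the whole pipeline can be exercised without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    picante,
    cluster,
    car
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
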