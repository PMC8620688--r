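Package: chemauth
Title: Chemometric Authentication of Foodstuffs from Multi-Elemental Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discriminating food varieties from ICP-OES
    multi-elemental concentration profiles. Implements the full
    chemometric authentication workflow: method-validation figures of
    merit (calibration linearity, background-equivalent-concentration
    based detection and quantification limits, spike recovery, precision
    RSD), univariate screening by one-way ANOVA with Fisher's LSD
    post-hoc test (from raw data or printed class summaries), principal
    component exploration, Duplex representative train/test splitting,
    NIPALS PLS2 discriminant analysis with stratified k-fold
    cross-validated latent-variable selection, Bayesian and LDA class
    assignment on predicted responses, and variable importance in
    projection (VIP) selection. Includes a synthetic-data generator
    parameterised by per-class summary statistics so the whole pipeline
    is testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
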