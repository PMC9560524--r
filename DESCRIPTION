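Package: agefba
Title: Enzyme-Constrained Flux Balance Analysis of Replicative Ageing in
    Budding Yeast
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools to study how the choice of objective function in flux
    balance analysis (FBA) shapes replicative ageing in budding yeast.
    Provides an enzyme-constrained FBA core (stoichiometric mass balance,
    kcat/molecular-weight enzyme coupling and a total protein pool), a
    deterministic lexicographic two-stage linear-programming optimiser with
    epsilon-flexibilities and a parsimonious post-optimisation, a pluggable
    Boolean regulation layer, a damage-accumulation lifespan simulator with
    asymmetric division, flux-rewiring analytics, and a generator plus
    calibration routine for miniature central-carbon networks with distinct
    fermentation and respiration routes and an oxidative-stress pathway.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
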