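Package: snakerisk
Title: Small-Area Snakebite Risk Mapping and Antivenom Accessibility
Version: 0.1.0
Authors@R: person("Maintainer", "Packaged", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Bayesian small-area disease mapping and healthcare accessibility
    analysis for snakebite envenoming. Fits a Poisson regression with an
    intrinsic conditional autoregressive (CAR) spatial random effect by
    Metropolis-within-Gibbs MCMC, derives smoothed incidence and posterior
    threshold-exceedance probabilities, compares smoothing methods by their
    ability to predict future high-incidence districts (ROC/AUC), classifies
    high-risk populations by incidence and by snake-habitat rules, and models
    travel time to treatment on a slope-penalised cost surface with
    multi-source shortest-path accumulation. A synthetic-world generator
    (district lattice, covariates, spatially correlated case counts, raster
    terrain with roads and facilities) makes the full pipeline testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
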