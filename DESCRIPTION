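Package: opennmix
Title: Density-Dependent Dynamic N-Mixture Models for Repeated Point Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits open-population (dynamic) N-mixture models to repeated
    point-count data with imperfect detection, where local population growth
    rate may depend on climate, experimental treatment and conspecific density.
    Provides an exact marginal likelihood over the latent abundance states via
    a forward algorithm, Bayesian fitting by Metropolis-within-Gibbs MCMC,
    WAIC-based multi-model selection with information-criterion weights, a
    principal-component climate gradient covariate, Moran's I residual
    diagnostics for spatial autocorrelation, and a synthetic-data generator
    emulating a playback-experiment study design on a regular survey grid.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
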