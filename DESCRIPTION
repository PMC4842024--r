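Package: pedpower
Title: Simulation-Based Power Analysis for Maternal Effects in Pedigreed
    Populations
Version: 0.1.0
Authors@R:
    person("pedpower", "maintainers", email = "pedpower@example.org",
           role = c("aut", "cre"))
Description: Tools for deciding whether a pedigreed study system carries
    enough structure to identify maternal genetic and maternal individual
    (environmental) effects.  Simulates Gaussian traits on a pedigree under
    nested animal models by gene dropping, fits Bayesian animal models with
    a conjugate blocked Gibbs sampler, and calibrates a DIC-based model
    choice test by Monte Carlo: a critical value for the DIC difference is
    taken from its null distribution, power is estimated along a grid of
    maternal variances, and the bias, coverage and omitted-effect
    consequences of the variance estimators are quantified.  Includes a
    synthetic generator emulating an insular passerine study system and a
    command-line interface for running full simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
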