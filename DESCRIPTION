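Package: bdrates
Title: Birth-Death Rate Estimation for Chemo-Sensitivity Dose-Response Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-parametric Bayesian analysis of in-vitro chemo-sensitivity
    experiments. Cell growth under compound treatment is modelled as a linear
    birth-death (Kendall) process whose per-cell division and death rates vary
    with log10 compound concentration under Gaussian-process priors, with a
    moment-matched Gaussian likelihood and an additive background-noise model.
    Posterior sampling is by Metropolis-within-Gibbs. The package estimates
    dose-specific birth and death rate curves with credible intervals, derives
    uncertainty-quantified potency summaries (GI50, TGI, LC50), provides
    conventional Gompertz and logistic sigmoid fits for comparison, an exact
    Gillespie simulator of the birth-death process, and a synthetic-experiment
    generator emulating a standard 9-dose triplicate assay design.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
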