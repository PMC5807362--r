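# Small experiment constructors shared across test files.

tiny_wells <- function(doses = c(-8, -6), reps = 2, n0 = 1000,
                       counts = NULL, id = "tiny") {
  z <- rep(doses, each = reps)
  if (is.null(counts)) counts <- n0 * exp(0.5) + seq_along(z)
  tibble::tibble(experiment_id = id, z_log10M = z, n0 = n0, count = counts)
}

tiny_experiment <- function(...) {
  bd_experiment(tiny_wells(...), background = c(18, 22, 19, 21))
}

# A quick fit on simulated data, small enough for unit tests.
quick_fit <- function(sim, n_iter = 3000, seed = 1, ...) {
  bd_fit(sim$experiment, n_iter = n_iter, n_burn = n_iter / 2,
         thin = 2, seed = seed, ...)
}

# Minimal hand-built fit object for summary-level tests: draws are given
# directly, bypassing MCMC.
fake_fit <- function(phi_lambda, phi_mu, doses, n0 = 1000,
                     hypers = NULL) {
  nd <- nrow(phi_lambda)
  if (is.null(hypers)) {
    hypers <- tibble::tibble(
      alpha_lambda = rowMeans(phi_lambda), alpha_mu = rowMeans(phi_mu),
      tau2_lambda = 1e-6, tau2_mu = 1e-6, l2_lambda = 2, l2_mu = 2,
      theta = 0, sigma2 = 1
    )
  }
  wells <- tibble::tibble(experiment_id = "fake",
                          z_log10M = rep(doses, 2),
                          n0 = n0, count = n0)
  structure(list(
    phi_lambda = phi_lambda, phi_mu = phi_mu, hypers = hypers,
    logpost = numeric(nd), doses = doses,
    experiment = bd_experiment(wells, c(-1, 1)),
    acceptance = list(),
    config = list(n_iter = nd, n_burn = 0, thin = 1, seed = 1)
  ), class = "bd_fit")
}
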