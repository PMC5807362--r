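logistic_ramp <- function(z, z50, w) 1 / (1 + exp(-(z - z50) / w))

# Named dose-response shapes for the per-cell rates. Defaults emulate the
# common assay picture: growth of roughly e^0.6-0.8 over the follow-up in
# untreated wells, birth suppressed and/or death induced at high dose.
scenario_rates <- function(scenario, params = list()) {
  p <- utils::modifyList(switch(
    scenario,
    constant = list(lambda0 = 1.0, mu0 = 0.4),
    quiescence = list(lambda0 = 0.01, mu0 = 0.01),
    turnover = list(lambda0 = 1.0, mu0 = 1.0),
    birth_inhibition = list(lambda_hi = 1.0, lambda_lo = 0.5, mu0 = 0.2,
                            z50 = -6.5, w = 0.5),
    death_induction = list(lambda0 = 1.0, mu_lo = 0.2, mu_hi = 0.9,
                           z50 = -6.5, w = 0.5),
    both = list(lambda_hi = 1.0, lambda_lo = 0.5, mu_lo = 0.2, mu_hi = 0.6,
                z50 = -6.5, w = 0.5),
    plateau = list(lambda_hi = 1.0, lambda_lo = 0.5, z50_birth = -8.0,
                   w_birth = 0.35, mu_lo = 0.2, mu_hi = 1.1,
                   z50_death = -5.2, w_death = 0.35),
    stop("unknown scenario: ", scenario)
  ), params)
  switch(
    scenario,
    constant = ,
    quiescence = ,
    turnover = list(
      lambda = function(z) rep(p$lambda0, length(z)),
      mu = function(z) rep(p$mu0, length(z))
    ),
    birth_inhibition = list(
      lambda = function(z) {
        p$lambda_lo + (p$lambda_hi - p$lambda_lo) *
          (1 - logistic_ramp(z, p$z50, p$w))
      },
      mu = function(z) rep(p$mu0, length(z))
    ),
    death_induction = list(
      lambda = function(z) rep(p$lambda0, length(z)),
      mu = function(z) p$mu_lo + (p$mu_hi - p$mu_lo) *
        logistic_ramp(z, p$z50, p$w)
    ),
    both = list(
      lambda = function(z) {
        p$lambda_lo + (p$lambda_hi - p$lambda_lo) *
          (1 - logistic_ramp(z, p$z50, p$w))
      },
      mu = function(z) p$mu_lo + (p$mu_hi - p$mu_lo) *
        logistic_ramp(z, p$z50, p$w)
    ),
    plateau = list(
      lambda = function(z) {
        p$lambda_lo + (p$lambda_hi - p$lambda_lo) *
          (1 - logistic_ramp(z, p$z50_birth, p$w_birth))
      },
      mu = function(z) p$mu_lo + (p$mu_hi - p$mu_lo) *
        logistic_ramp(z, p$z50_death, p$w_death)
    )
  )
}

#' Simulate a chemo-sensitivity experiment with known ground truth
#'
#' Generates a complete experiment in the standard screening design: a
#' log-spaced dose series (default 9 doses over log10 M in \[-9, -4\]) with
#' replicate wells (default triplicate), plus compound-free background
#' wells. Each well's final count is an exact Gillespie draw of the linear
#' birth-death process at that dose's per-cell rates, plus additive Gaussian
#' background noise N(theta, sigma^2); background wells are pure noise.
#' True rate curves and the true GI50/TGI/LC50 (solved on the noiseless mean
#' curve with the min-dose control convention) are returned alongside.
#'
#' Named scenarios: `"constant"`, `"quiescence"` (rates near 0),
#' `"turnover"` (large matched rates - same means as quiescence, far larger
#' variance), `"birth_inhibition"` (sigmoidal drop in the birth rate),
#' `"death_induction"` (sigmoidal rise in the death rate), `"both"` (birth
#' halves and death triples across the range), `"plateau"` (two separated
#' transitions, giving a non-sigmoid mean curve with a mid-range shelf).
#' Custom `lambda_fn` / `mu_fn` override the named shapes.
#'
#' @param scenario Scenario name (see Details).
#' @param params Named list overriding the scenario's shape parameters.
#' @param doses Dose grid, log10 M.
#' @param replicates Wells per dose.
#' @param n0 Initial cells per well (scalar or one per well).
#' @param theta,sigma Background-noise mean and standard deviation (counts).
#' @param n_background Number of background wells (>= 2).
#' @param lambda_fn,mu_fn Optional rate functions of z, overriding
#'   `scenario`.
#' @param experiment_id Identifier written into the wells table.
#' @param seed Optional integer seed.
#' @param cap Gillespie population cap.
#' @return A list of class `"bd_sim"` with elements `experiment` (a
#'   [bd_experiment()]), and `truth`: a list with `curves` (tibble of z,
#'   lambda, mu, mean on a dense grid), `potency` (tibble of true
#'   GI50/TGI/LC50 in log10 M and M), `theta`, `sigma2`, and the rate
#'   functions.
#' @examples
#' sim <- simulate_experiment("both", seed = 1)
#' sim$experiment
#' sim$truth$potency
#' @export
simulate_experiment <- function(scenario = "both", params = list(),
                                doses = seq(-9, -4, length.out = 9),
                                replicates = 3, n0 = 1000,
                                theta = 20, sigma = 10,
                                n_background = 16,
                                lambda_fn = NULL, mu_fn = NULL,
                                experiment_id = scenario,
                                seed = NULL, cap = 1e8) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(doses) >= 2L, !anyDuplicated(doses), replicates >= 1L,
            n_background >= 2L, sigma >= 0)
  if (is.null(lambda_fn) || is.null(mu_fn)) {
    shapes <- scenario_rates(scenario, params)
    if (is.null(lambda_fn)) lambda_fn <- shapes$lambda
    if (is.null(mu_fn)) mu_fn <- shapes$mu
  }
  doses <- sort(doses)
  zw <- rep(doses, each = replicates)
  n0w <- rep_len(n0, length(zw))
  lam_w <- lambda_fn(zw)
  mu_w <- mu_fn(zw)
  if (any(lam_w < 0) || any(mu_w < 0)) {
    stop("rate curves must be non-negative over the dose range")
  }
  counts <- vapply(seq_along(zw), function(i) {
    .bdp_gillespie(1L, n0w[i], lam_w[i], mu_w[i], 1.0, cap)
  }, numeric(1))
  counts <- counts + rnorm(length(counts), theta, sigma)
  wells <- tibble::tibble(experiment_id = experiment_id, z_log10M = zw,
                          n0 = n0w, count = counts)
  bg <- rnorm(n_background, theta, sigma)
  exp_obj <- bd_experiment(wells, bg,
                           metadata = list(scenario = scenario, t = 1))

  zg <- seq(min(doses), max(doses), length.out = 201)
  lam_g <- lambda_fn(zg); mu_g <- mu_fn(zg)
  n0_ref <- mean(n0w)
  m_g <- n0_ref * exp(lam_g - mu_g)
  truth_curves <- tibble::tibble(z = zg, lambda = lam_g, mu = mu_g,
                                 mean = m_g)
  pot <- purrr::map_dfr(c("GI50", "TGI", "LC50"), function(kind) {
    cr <- curve_potency(zg, m_g, n0_ref, kind, g_control = m_g[1] - n0_ref)
    tibble::tibble(kind = kind, z_log10M = cr$z, conc_M = 10^cr$z,
                   censor = cr$censor)
  })
  structure(list(
    experiment = exp_obj,
    truth = list(curves = truth_curves, potency = pot, theta = theta,
                 sigma2 = sigma^2, lambda_fn = lambda_fn, mu_fn = mu_fn,
                 n0_ref = n0_ref, scenario = scenario)
  ), class = "bd_sim")
}

#' @export
print.bd_sim <- function(x, ...) {
  cat("<bd_sim> scenario:", x$truth$scenario, "\n")
  print(x$experiment)
  invisible(x)
}
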