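#' Extinction and offspring probabilities of the linear birth-death process
#'
#' For a Kendall (linear birth-death) process with per-cell birth rate
#' `lambda` and death rate `mu`, the distribution of the count at time `t`
#' started from a single cell is governed by two probabilities
#' \deqn{\alpha(t) = \frac{\mu(e^{(\lambda-\mu)t} - 1)}{\lambda e^{(\lambda-\mu)t} - \mu},
#'       \qquad
#'       \beta(t) = \frac{\lambda(e^{(\lambda-\mu)t} - 1)}{\lambda e^{(\lambda-\mu)t} - \mu},}
#' the probability of extinction and the "offspring" parameter of the
#' geometric tail, respectively. On the critical line \eqn{\lambda = \mu}
#' both reduce to the analytic limit \eqn{\lambda t / (1 + \lambda t)}, which
#' is used when \eqn{|\lambda - \mu| < 10^{-8}} to keep the evaluation
#' continuous and numerically stable there.
#'
#' @param lambda Per-cell birth rate, >= 0.
#' @param mu Per-cell death rate, >= 0.
#' @param t Elapsed time, >= 0.
#' @return A named numeric vector `c(alpha = , beta = )`, each in \[0, 1\].
#' @examples
#' bdp_alpha_beta(0, 1, 1)      # pure death: alpha = 1 - exp(-1)
#' bdp_alpha_beta(0.5, 0.5, 1)  # critical case: both 1/3
#' @export
bdp_alpha_beta <- function(lambda, mu, t) {
  stopifnot(is.numeric(lambda), is.numeric(mu), is.numeric(t),
            length(lambda) == 1L, length(mu) == 1L, length(t) == 1L,
            is.finite(lambda), is.finite(mu), is.finite(t))
  if (lambda < 0 || mu < 0) stop("rates must be non-negative")
  if (t < 0) stop("t must be non-negative")
  if (t == 0 || (lambda == 0 && mu == 0)) {
    return(c(alpha = 0, beta = 0))
  }
  if (abs(lambda - mu) < 1e-8) {
    a <- lambda * t / (1 + lambda * t)
    return(c(alpha = a, beta = a))
  }
  d <- lambda - mu
  # expm1 keeps precision when (lambda - mu) t is small
  em1 <- expm1(d * t)
  denom <- lambda * (em1 + 1) - mu
  c(alpha = mu * em1 / denom, beta = lambda * em1 / denom)
}

#' Transition probability of the Kendall process
#'
#' Exact probability \eqn{P_{ab}(t) = \Pr(N(t) = b \mid N(0) = a)} for the
#' linear birth-death process,
#' \deqn{P_{ab}(t) = \sum_{j=0}^{\min(a,b)} \binom{a}{j}\binom{a+b-j-1}{a-1}
#'       \alpha^{a-j} \beta^{b-j} (1-\alpha-\beta)^j.}
#' Binomial coefficients are evaluated through log-gamma and each term is
#' exponentiated with its sign (\eqn{1-\alpha-\beta} may be negative); the
#' signed sum is accumulated in extended precision because the terms can
#' exceed the result by orders of magnitude. The sum stays finite for
#' counts far beyond the direct-factorial range. This is
#' a validation/oracle path: the fitting routines use the moment-matched
#' Gaussian approximation instead, because the combinatorial sum is
#' impractical at assay-scale counts.
#'
#' The process is extended to `a = 0` as an absorbing state:
#' \eqn{P_{0b} = 1} if `b = 0`, else 0.
#'
#' @param a Initial count (non-negative integer).
#' @param b Final count (non-negative integer).
#' @inheritParams bdp_alpha_beta
#' @return The transition probability, a number in \[0, 1\].
#' @examples
#' bdp_transition_prob(1, 0, lambda = 0, mu = 1, t = 1)  # 1 - exp(-1)
#' bdp_transition_prob(3, 3, lambda = 0, mu = 0, t = 1)  # 1
#' @export
bdp_transition_prob <- function(a, b, lambda, mu, t) {
  stopifnot(length(a) == 1L, length(b) == 1L,
            a >= 0, b >= 0, a == round(a), b == round(b))
  if (a == 0) return(as.numeric(b == 0))
  ab <- bdp_alpha_beta(lambda, mu, t)
  .bdp_transition_sum(as.integer(a), as.integer(b),
                      ab[["alpha"]], ab[["beta"]])
}

#' Mean and variance of the birth-death count
#'
#' Closed-form moments of \eqn{N(t)} given \eqn{N(0) = n_0}:
#' \deqn{m_t = n_0 e^{(\lambda-\mu)t}, \qquad
#'       v_t = n_0 \frac{\lambda+\mu}{\lambda-\mu}
#'             e^{(\lambda-\mu)t}\left(e^{(\lambda-\mu)t} - 1\right).}
#' The variance has a removable singularity at \eqn{\lambda = \mu}; the
#' analytic limit \eqn{v_t = n_0(\lambda+\mu)t} is substituted when
#' \eqn{|\lambda-\mu| < 10^{-8}}, and `expm1` is used elsewhere so the
#' evaluation is continuous across the critical line.
#'
#' @param n0 Initial count, > 0 (real-valued; assay intensities are allowed).
#' @inheritParams bdp_alpha_beta
#' @return A named numeric vector `c(mean = , var = )`.
#' @examples
#' bdp_moments(100, 0.7, 0.2, 1)     # mean 100 * exp(0.5)
#' bdp_moments(100, 0.5, 0.5, 1)     # critical: var = 100
#' @export
bdp_moments <- function(n0, lambda, mu, t = 1) {
  stopifnot(length(n0) == 1L, n0 > 0)
  if (lambda < 0 || mu < 0) stop("rates must be non-negative")
  if (t < 0) stop("t must be non-negative")
  d <- lambda - mu
  m <- n0 * exp(d * t)
  if (abs(d) < 1e-8) {
    v <- n0 * (lambda + mu) * t
  } else {
    v <- n0 * (lambda + mu) * exp(d * t) * expm1(d * t) / d
  }
  c(mean = m, var = v)
}

#' Dose-level moments with the follow-up time absorbed
#'
#' In a chemo-sensitivity assay the follow-up duration is common to all
#' doses, so it is absorbed into the rates (t = 1 by convention): `lambda`
#' and `mu` are per-cell birth and death rates over the whole experiment.
#'
#' @inheritParams bdp_moments
#' @return A named numeric vector `c(mean = , var = )`.
#' @export
bdp_dose_moments <- function(n0, lambda, mu) bdp_moments(n0, lambda, mu, t = 1)

# Vectorised moment evaluation used in likelihood loops: lambda/mu/n0 may be
# vectors of equal length. Returns list(mean=, var=).
dose_moments_vec <- function(n0, lambda, mu) {
  d <- lambda - mu
  m <- n0 * exp(d)
  s <- lambda + mu
  v <- ifelse(abs(d) < 1e-8, n0 * s, n0 * s * exp(d) * expm1(d) / d)
  list(mean = m, var = v)
}

#' Log-likelihood of a chemo-sensitivity experiment
#'
#' Observed well counts are modelled as the birth-death count plus additive
#' background noise, \eqn{X = N + \epsilon} with
#' \eqn{\epsilon \sim N(\theta, \sigma^2)}, and the birth-death count is
#' approximated by a Gaussian with matched mean and variance (accurate for
#' the large initial counts typical of these assays). The log-likelihood is
#' \deqn{\sum_i \log f_N(x_i \mid m(n_{0i}, z_i) + \theta,
#'              v(n_{0i}, z_i) + \sigma^2)
#'       + \sum_j \log f_N(e_j \mid \theta, \sigma^2),}
#' where the second sum runs over compound-free background wells.
#'
#' @param wells A data frame with columns `z_log10M`, `n0`, `count`
#'   (one row per well; replicate wells repeat a dose).
#' @param background Numeric vector of background-noise measurements.
#' @param lambda,mu Named numeric vectors of per-cell rates, one entry per
#'   distinct dose; names are the dose values as formatted by
#'   `format_dose()` internally, or unnamed vectors ordered by sorted
#'   distinct dose.
#' @param theta Background-noise mean.
#' @param sigma2 Background-noise variance, > 0.
#' @return The log-likelihood (a finite scalar for valid inputs).
#' @export
bd_loglik <- function(wells, background, lambda, mu, theta, sigma2) {
  if (!is.numeric(sigma2) || length(sigma2) != 1L || sigma2 <= 0) {
    stop("sigma2 must be a positive scalar")
  }
  doses <- sort(unique(wells$z_log10M))
  if (length(lambda) != length(doses) || length(mu) != length(doses)) {
    stop("need one (lambda, mu) pair per distinct dose")
  }
  idx <- match(wells$z_log10M, doses)
  mom <- dose_moments_vec(wells$n0, lambda[idx], mu[idx])
  ll <- sum(dnorm(wells$count, mean = mom$mean + theta,
                  sd = sqrt(mom$var + sigma2), log = TRUE))
  if (length(background)) {
    ll <- ll + sum(dnorm(background, mean = theta, sd = sqrt(sigma2),
                         log = TRUE))
  }
  ll
}

#' Simulate final counts of the linear birth-death process
#'
#' Exact Gillespie simulation: a population of k cells has aggregate birth
#' and death rates \eqn{k\lambda} and \eqn{k\mu}; events are drawn one at a
#' time until the follow-up time elapses or the population dies out. This is
#' the ground-truth oracle behind the transition-probability and moment
#' checks, and the engine of the synthetic-experiment generator.
#'
#' @inheritParams bdp_moments
#' @param n0 Initial count, >= 0 (integer-valued).
#' @param nsim Number of independent trajectories.
#' @param cap Abort if the population exceeds this size (runaway growth).
#' @param seed Optional integer seed (calls [set.seed()]).
#' @return Numeric vector of `nsim` final counts.
#' @examples
#' simulate_bdp(50, 0, 0, t = 1, nsim = 3)   # no events: all 50
#' @export
simulate_bdp <- function(n0, lambda, mu, t = 1, nsim = 1, cap = 1e8,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  .bdp_gillespie(as.integer(nsim), as.double(n0), as.double(lambda),
                 as.double(mu), as.double(t), as.double(cap))
}
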