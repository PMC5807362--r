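#' Squared-exponential covariance matrix
#'
#' Evaluates the kernel \eqn{K(z, z') = \tau^2 \exp(-(z-z')^2 / \ell^2)} on a
#' grid of log10 concentrations and adds a small diagonal jitter so the
#' Cholesky factorisation succeeds on dense, nearly collinear grids. The
#' jitter starts at `jitter * tau2` and escalates tenfold up to three times
#' before giving up.
#'
#' @param z Numeric grid (log10 M).
#' @param tau2 Kernel variance, > 0.
#' @param l2 Squared length-scale, > 0 (units of squared log10 M).
#' @param jitter Relative diagonal jitter (default 1e-8).
#' @return A symmetric positive-definite matrix with attribute `"chol"`
#'   holding its upper-triangular Cholesky factor.
#' @examples
#' sq_exp_kernel(c(0, 1), tau2 = 1, l2 = 1)  # off-diagonal exp(-1)
#' @export
sq_exp_kernel <- function(z, tau2, l2, jitter = 1e-8) {
  stopifnot(length(z) >= 1L, is.finite(z), tau2 > 0, l2 > 0)
  d2 <- outer(z, z, function(a, b) (a - b)^2)
  K <- tau2 * exp(-d2 / l2)
  eps <- jitter * tau2
  for (try in 0:3) {
    R <- tryCatch(chol(K + diag(eps, length(z))), error = function(e) NULL)
    if (!is.null(R)) {
      K <- K + diag(eps, length(z))
      attr(K, "chol") <- R
      return(K)
    }
    eps <- eps * 10
  }
  stop("kernel matrix is not positive definite even after jitter escalation")
}

#' Default hyperprior configuration
#'
#' Priors on the hierarchy above the latent log-rate curves: the GP means
#' get mean-zero Gaussian priors with variance `s_alpha2`, the kernel
#' variances tau^2 get Inverse-Gamma(a1, b1) priors, the squared
#' length-scales l^2 get Gamma(a2, b2) priors, the noise mean theta gets an
#' improper flat prior and the noise variance sigma^2 the improper
#' log-uniform p(sigma^2) proportional to 1/sigma^2. Each rate curve
#' (birth, death) has its own copy of the proper-prior constants.
#'
#' The default `s_alpha2 = 2.25` (sd 1.5 on the log rate) is weakly
#' informative on the biological scale: per-experiment rates within
#' e^(+/-3), i.e. roughly 0.05-20 events per cell over the follow-up,
#' which covers every plausible chemo-sensitivity response. Much wider
#' mean priors place substantial mass on "rate effectively zero" curves
#' whose dynamics leave no trace in the counts, which both destabilises
#' sampling and lets the background-noise variance absorb the
#' birth-death variance. The kernel defaults (tau^2 ~ IG(2,1), mean 1;
#' l^2 ~ Gamma(2,1), mean 2 squared decades) are zero-avoiding and
#' calibrated on the synthetic scenarios: they support amplitudes up to
#' several e-folds across the tested range and features at the 0.5-1.5
#' decade scale typical of dose-response transitions, while discouraging
#' sub-replicate-noise wiggles and runaway amplitudes that make interval
#' estimates overconfident.
#'
#' @param s_alpha2_lambda,s_alpha2_mu Prior variances of the GP means.
#' @param a1_lambda,b1_lambda,a1_mu,b1_mu Inverse-Gamma shape/rate for tau^2.
#' @param a2_lambda,b2_lambda,a2_mu,b2_mu Gamma shape/rate for l^2.
#' @return A named list of class `"bd_hyperprior"`.
#' @export
bd_hyperprior <- function(s_alpha2_lambda = 2.25, s_alpha2_mu = 2.25,
                          a1_lambda = 2, b1_lambda = 1,
                          a1_mu = 2, b1_mu = 1,
                          a2_lambda = 2, b2_lambda = 1,
                          a2_mu = 2, b2_mu = 1) {
  cfg <- list(s_alpha2_lambda = s_alpha2_lambda, s_alpha2_mu = s_alpha2_mu,
              a1_lambda = a1_lambda, b1_lambda = b1_lambda,
              a1_mu = a1_mu, b1_mu = b1_mu,
              a2_lambda = a2_lambda, b2_lambda = b2_lambda,
              a2_mu = a2_mu, b2_mu = b2_mu)
  if (any(vapply(cfg, function(x) !is.numeric(x) || length(x) != 1L || x <= 0,
                 logical(1)))) {
    stop("all hyperprior constants must be positive scalars")
  }
  structure(cfg, class = "bd_hyperprior")
}

# Inverse-Gamma(a, b) log-density (rate parameterisation).
dinvgamma_log <- function(x, a, b) {
  ifelse(x > 0, a * log(b) - lgamma(a) - (a + 1) * log(x) - b / x, -Inf)
}

#' Log hyperprior density
#'
#' Sum of the log prior densities of all hyperparameters, up to the additive
#' constants of the improper priors on `theta` (flat, contributes 0) and
#' `sigma2` (log-uniform, contributes `-log(sigma2)`). Non-positive values
#' of `tau2`, `l2` or `sigma2` return `-Inf` (rejection semantics).
#'
#' @param hypers Named list or vector with elements `alpha_lambda`,
#'   `alpha_mu`, `tau2_lambda`, `tau2_mu`, `l2_lambda`, `l2_mu`, `theta`,
#'   `sigma2`.
#' @param config A [bd_hyperprior()] configuration.
#' @return Scalar log-density (possibly `-Inf`).
#' @export
bd_log_hyperprior <- function(hypers, config = bd_hyperprior()) {
  h <- as.list(hypers)
  if (h$tau2_lambda <= 0 || h$tau2_mu <= 0 || h$l2_lambda <= 0 ||
      h$l2_mu <= 0 || h$sigma2 <= 0) {
    return(-Inf)
  }
  dnorm(h$alpha_lambda, 0, sqrt(config$s_alpha2_lambda), log = TRUE) +
    dnorm(h$alpha_mu, 0, sqrt(config$s_alpha2_mu), log = TRUE) +
    dinvgamma_log(h$tau2_lambda, config$a1_lambda, config$b1_lambda) +
    dinvgamma_log(h$tau2_mu, config$a1_mu, config$b1_mu) +
    stats::dgamma(h$l2_lambda, shape = config$a2_lambda,
                  rate = config$b2_lambda, log = TRUE) +
    stats::dgamma(h$l2_mu, shape = config$a2_mu, rate = config$b2_mu,
                  log = TRUE) -
    log(h$sigma2)
}

# One MVN draw with mean vector m and covariance carrying its Cholesky
# factor in attr(K, "chol"); z optional standard-normal input.
mvn_draw <- function(m, K, z = NULL) {
  R <- attr(K, "chol")
  if (is.null(R)) R <- chol(K)
  if (is.null(z)) z <- rnorm(length(m))
  as.numeric(m + crossprod(R, z))
}

#' Draw latent log-rate curves from the Gaussian-process prior
#'
#' The finite marginal of the GP prior on a grid is multivariate normal:
#' \eqn{\phi_\lambda \sim MVN(\alpha_\lambda 1, K_\lambda)} and
#' \eqn{\phi_\mu \sim MVN(\alpha_\mu 1, K_\mu)}, independent of each other.
#'
#' @param z Dose grid (log10 M), strictly increasing.
#' @param hypers Named list with `alpha_lambda`, `alpha_mu`, `tau2_lambda`,
#'   `tau2_mu`, `l2_lambda`, `l2_mu`.
#' @param seed Optional integer seed.
#' @return A tibble with columns `z`, `phi_lambda`, `phi_mu`.
#' @export
bd_sample_latent_prior <- function(z, hypers, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(diff(z) > 0))
  h <- as.list(hypers)
  Kl <- sq_exp_kernel(z, h$tau2_lambda, h$l2_lambda)
  Km <- sq_exp_kernel(z, h$tau2_mu, h$l2_mu)
  tibble::tibble(
    z = z,
    phi_lambda = mvn_draw(rep(h$alpha_lambda, length(z)), Kl),
    phi_mu = mvn_draw(rep(h$alpha_mu, length(z)), Km)
  )
}

# GP conditional of the latent curve at `zstar` given values `phi` at `z`,
# under a shared mean alpha and kernel (tau2, l2). Returns list(mean, cov)
# with cov carrying its Cholesky when `draw`-ready.
gp_conditional <- function(zstar, z, phi, alpha, tau2, l2, jitter = 1e-8) {
  Kzz <- sq_exp_kernel(z, tau2, l2, jitter)
  R <- attr(Kzz, "chol")
  Ksz <- tau2 * exp(-outer(zstar, z, function(a, b) (a - b)^2) / l2)
  Kss <- tau2 * exp(-outer(zstar, zstar, function(a, b) (a - b)^2) / l2)
  # solve K^{-1} (phi - alpha) and K^{-1} t(Ksz) through the Cholesky
  dev <- phi - alpha
  w <- backsolve(R, forwardsolve(t(R), dev))
  V <- backsolve(R, forwardsolve(t(R), t(Ksz)))
  mean_s <- alpha + as.numeric(Ksz %*% w)
  cov_s <- Kss - Ksz %*% V
  cov_s <- (cov_s + t(cov_s)) / 2
  list(mean = mean_s, cov = cov_s)
}

# Draw from the GP conditional; adds escalating jitter for the conditional
# covariance, which is often numerically singular at interpolation points.
gp_conditional_draw <- function(zstar, z, phi, alpha, tau2, l2) {
  cond <- gp_conditional(zstar, z, phi, alpha, tau2, l2)
  eps <- 1e-10 * max(tau2, 1e-12)
  for (try in 0:4) {
    R <- tryCatch(chol(cond$cov + diag(eps, length(zstar))),
                  error = function(e) NULL)
    if (!is.null(R)) {
      return(as.numeric(cond$mean + crossprod(R, rnorm(length(zstar)))))
    }
    eps <- eps * 100
  }
  # fully degenerate conditional: fall back on the mean
  cond$mean
}
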