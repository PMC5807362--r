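test_that("alpha/beta probabilities match closed forms and limits", {
  # pure death: extinction probability 1 - exp(-mu t), no births
  ab <- bdp_alpha_beta(0, 1, 1)
  expect_equal(ab[["alpha"]], 1 - exp(-1), tolerance = 1e-12)
  expect_equal(ab[["beta"]], 0)

  # critical line: analytic limit lambda*t / (1 + lambda*t), and the
  # generic formula approaches it continuously from nearby rates
  ab_crit <- bdp_alpha_beta(0.5, 0.5, 1)
  expect_equal(unname(ab_crit), c(1 / 3, 1 / 3), tolerance = 1e-12)
  ab_near <- bdp_alpha_beta(0.5 + 1e-6, 0.5, 1)
  expect_equal(unname(ab_near), unname(ab_crit), tolerance = 1e-5)

  # t = 0: no events can have happened
  expect_equal(unname(bdp_alpha_beta(2, 3, 0)), c(0, 0))
  # degenerate process
  expect_equal(unname(bdp_alpha_beta(0, 0, 5)), c(0, 0))

  # bounds hold over a parameter sweep
  for (lam in c(0, 0.1, 1, 3)) {
    for (mu in c(0, 0.1, 1, 3)) {
      ab <- bdp_alpha_beta(lam, mu, 1)
      expect_true(all(ab >= 0 & ab <= 1))
    }
  }
  expect_error(bdp_alpha_beta(1, 1, -1), "non-negative")
})

test_that("transition probabilities are exact in known cases", {
  # one cell, pure death: P(extinct by t=1) = 1 - exp(-1)
  expect_equal(bdp_transition_prob(1, 0, 0, 1, 1), 1 - exp(-1),
               tolerance = 1e-12)
  # frozen process stays put
  expect_equal(bdp_transition_prob(3, 3, 0, 0, 1), 1)
  expect_equal(bdp_transition_prob(3, 2, 0, 0, 1), 0)
  # absorbing extension at a = 0
  expect_equal(bdp_transition_prob(0, 0, 0.5, 0.5, 1), 1)
  expect_equal(bdp_transition_prob(0, 4, 0.5, 0.5, 1), 0)
})

test_that("transition probabilities sum to one over the final count", {
  for (a in c(1, 5, 20)) {
    for (r in list(c(0.5, 0.5), c(2, 1), c(0.2, 1.5))) {
      b_max <- 60 + a * 12
      total <- sum(vapply(0:b_max, function(b) {
        bdp_transition_prob(a, b, r[1], r[2], 1)
      }, numeric(1)))
      expect_equal(total, 1, tolerance = 1e-8)
    }
  }
})

test_that("transition probability matches Gillespie frequencies", {
  n <- 2e5
  x <- simulate_bdp(2, 0.6, 0.3, t = 1, nsim = n, seed = 42)
  for (b in c(0, 1, 2, 3, 5)) {
    p_hat <- mean(x == b)
    p <- bdp_transition_prob(2, b, 0.6, 0.3, 1)
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(p_hat - p), 4 * se + 1e-12)
  }
})

test_that("moments follow the closed forms, including the critical limit", {
  expect_equal(unname(bdp_moments(100, 0, 0, 1)), c(100, 0))
  m <- bdp_moments(100, 0.7, 0.2, 1)
  expect_equal(m[["mean"]], 100 * exp(0.5), tolerance = 1e-12)
  expect_equal(m[["var"]],
               100 * 0.9 / 0.5 * exp(0.5) * (exp(0.5) - 1),
               tolerance = 1e-12)
  # critical limit v = n0 (lambda + mu) t
  expect_equal(bdp_moments(100, 0.5, 0.5, 1)[["var"]], 100)
  # continuity across the critical line (finite-difference approach)
  eps <- 10^-(4:7)
  v_eps <- vapply(eps, function(e) bdp_moments(100, 0.5 + e, 0.5, 1)[["var"]],
                  numeric(1))
  expect_true(all(abs(v_eps - 100) < 100 * 2 * eps / 0.5 + 1e-6))
  # dose-level wrapper is the t = 1 case
  expect_equal(bdp_dose_moments(250, 0.7, 0.2), bdp_moments(250, 0.7, 0.2, 1))
})

test_that("variance separates quiescence from matched turnover", {
  # identical means, variance ratio exactly the rate-sum ratio in the
  # critical limit
  v_hi <- bdp_moments(1000, 1, 1, 1)[["var"]]
  v_lo <- bdp_moments(1000, 0.01, 0.01, 1)[["var"]]
  expect_equal(bdp_moments(1000, 1, 1, 1)[["mean"]],
               bdp_moments(1000, 0.01, 0.01, 1)[["mean"]])
  expect_equal(v_hi / v_lo, 100)
})

test_that("Gillespie simulator matches closed-form moments", {
  expect_equal(simulate_bdp(50, 0, 0, t = 1, nsim = 5), rep(50, 5))

  # pure death from one cell: extinction fraction
  n <- 1e5
  x <- simulate_bdp(1, 0, 1, t = 1, nsim = n, seed = 7)
  p <- 1 - exp(-1)
  expect_lt(abs(mean(x == 0) - p), 4 * sqrt(p * (1 - p) / n))

  # supercritical growth: empirical mean and variance
  y <- simulate_bdp(100, 0.7, 0.2, t = 1, nsim = 5e4, seed = 8)
  mo <- bdp_moments(100, 0.7, 0.2, 1)
  expect_lt(abs(mean(y) - mo[["mean"]]),
            4 * sqrt(mo[["var"]] / 5e4))
  expect_lt(abs(var(y) - mo[["var"]]), 4 * mo[["var"]] * sqrt(2 / 5e4))

  # reproducible under seed
  expect_identical(simulate_bdp(30, 1, 0.5, nsim = 10, seed = 3),
                   simulate_bdp(30, 1, 0.5, nsim = 10, seed = 3))
  expect_error(simulate_bdp(10, 5, 0, t = 10, nsim = 1, cap = 1e3, seed = 1),
               "cap")
})

test_that("experiment log-likelihood matches an independent transcription", {
  set.seed(5)
  wells <- tibble::tibble(
    experiment_id = "ll", z_log10M = rep(c(-8, -6.5, -5), each = 2),
    n0 = c(900, 1100, 1000, 1000, 950, 1050),
    count = c(1500, 1700, 1100, 1050, 600, 640)
  )
  bg <- c(15, 25, 22)
  lam <- c(0.9, 0.6, 0.3); mu <- c(0.2, 0.35, 0.7)
  theta <- 20; sig2 <- 150
  # literal term-by-term transcription of the likelihood
  doses <- sort(unique(wells$z_log10M))
  manual <- 0
  for (i in seq_len(nrow(wells))) {
    j <- match(wells$z_log10M[i], doses)
    d <- lam[j] - mu[j]
    m <- wells$n0[i] * exp(d)
    v <- wells$n0[i] * (lam[j] + mu[j]) / d * exp(d) * (exp(d) - 1)
    manual <- manual +
      dnorm(wells$count[i], m + theta, sqrt(v + sig2), log = TRUE)
  }
  for (e in bg) manual <- manual + dnorm(e, theta, sqrt(sig2), log = TRUE)
  expect_equal(bd_loglik(wells, bg, lam, mu, theta, sig2), manual,
               tolerance = 1e-12)

  # observation exactly at the modelled mean, no background wells
  one <- wells[1, ]; j <- 1
  d <- lam[j] - mu[j]
  m <- one$n0 * exp(d)
  v <- one$n0 * (lam[j] + mu[j]) / d * exp(d) * (exp(d) - 1)
  one$count <- m + theta
  expect_equal(bd_loglik(one, numeric(0), lam[1], mu[1], theta, sig2),
               -0.5 * log(2 * pi * (v + sig2)), tolerance = 1e-12)

  # degenerate process reduces to iid Normal(n0 + theta, sig2)
  wells0 <- wells; lam0 <- rep(0, 3); mu0 <- rep(0, 3)
  expect_equal(
    bd_loglik(wells0, numeric(0), lam0, mu0, 0, sig2),
    sum(dnorm(wells0$count, wells0$n0, sqrt(sig2), log = TRUE)),
    tolerance = 1e-12
  )
  expect_error(bd_loglik(wells, bg, lam, mu, theta, -1), "positive")
  expect_error(bd_loglik(wells, bg, lam[1:2], mu[1:2], theta, sig2),
               "per distinct dose")
})

test_that("normal approximation is close for large initial counts", {
  for (n0 in c(100, 1000)) {
    x <- simulate_bdp(n0, 0.8, 0.3, t = 1, nsim = 2e4, seed = n0)
    mo <- bdp_moments(n0, 0.8, 0.3, 1)
    ks <- suppressWarnings(
      ks.test(x, "pnorm", mean = mo[["mean"]], sd = sqrt(mo[["var"]]))
    )
    expect_lt(unname(ks$statistic), 0.05)
  }
})
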