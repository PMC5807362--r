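test_that("crossing solver finds the smallest crossing by interpolation", {
  z <- seq(-9, -4, length.out = 11)
  y <- seq(2000, 0, length.out = 11)
  cr <- bdrates:::first_crossing(z, y, 1000)
  expect_equal(cr$z, -6.5, tolerance = 1e-9)
  expect_equal(cr$n, 1L)
  # exact hit at the first grid point
  expect_equal(bdrates:::first_crossing(z, y, 2000)$z, -9)
  # no crossing: side is reported
  expect_true(is.na(bdrates:::first_crossing(z, y, 3000)$z))
  expect_equal(bdrates:::first_crossing(z, y, 3000)$side, "below")
  expect_equal(bdrates:::first_crossing(z, y, -1)$side, "above")
  # wiggly curve: smallest of several crossings wins and all are counted
  yw <- c(5, -1, 2, -3, 1, -1, 2, -1, 1, -2, 1)
  crw <- bdrates:::first_crossing(z, yw, 0)
  expect_gt(crw$n, 1L)
  expect_lt(crw$z, z[2])
})

test_that("analytic potency: exponential decline has an exact TGI", {
  # m(z) = n0 exp(1 - (z - z_min)) crosses m = n0 at z = z_min + 1
  z <- seq(-9, -6, length.out = 400)
  n0 <- 1000
  m <- n0 * exp(1 - (z + 9))
  cr <- bdrates:::curve_potency(z, m, n0, "TGI", g_control = m[1] - n0)
  expect_equal(cr$z, -8, tolerance = 1e-4)
  # LC50: crosses n0/2 at 1 + log(2)
  cr2 <- bdrates:::curve_potency(z, m, n0, "LC50", g_control = m[1] - n0)
  expect_equal(cr2$z, -8 + log(2), tolerance = 1e-4)
})

test_that("flat doubling curve censors all three summaries above range", {
  z <- seq(-9, -4, length.out = 50)
  m <- rep(2000, 50)
  for (kind in c("GI50", "TGI", "LC50")) {
    cr <- bdrates:::curve_potency(z, m, 1000, kind, g_control = 1000)
    expect_true(is.na(cr$z))
    expect_equal(cr$censor, "above_range")
  }
  # shrinking control growth makes GI50 undefined
  cr <- bdrates:::curve_potency(z, m, 1000, "GI50", g_control = -5)
  expect_equal(cr$censor, "control_nonpositive")
})

test_that("equal-quantile interval uses symmetric order statistics", {
  x <- 1:1000
  ci <- bdrates:::eq_quantile_ci(x)
  expect_equal(ci, c(25, 976))
  # interval from a subsample is never narrower in expectation: check the
  # stochastic sanity property on one resample chain
  set.seed(1)
  x <- rnorm(4000)
  w_full <- diff(bdrates:::eq_quantile_ci(x))
  w_sub <- mean(replicate(50, diff(bdrates:::eq_quantile_ci(sample(x, 200)))))
  expect_lt(w_sub, w_full * 1.1)
})

test_that("identical draws collapse the curve bands to zero width", {
  doses <- seq(-9, -4, length.out = 5)
  phi_l <- matrix(rep(log(c(1, 0.9, 0.7, 0.5, 0.4)), each = 120), 120, 5,
                  byrow = FALSE)
  phi_m <- matrix(log(0.2), 120, 5)
  fit <- fake_fit(phi_l, phi_m, doses)
  cv <- bd_curves(fit, n0_ref = 1000, grid_size = 30)
  expect_s3_class(cv, "bd_curves")
  expect_lt(max(cv$m_hi - cv$m_lo), 1e-3 * max(cv$m_mean))
  # at the tested doses the mean curve equals the draw's curve
  at <- cv[cv$z %in% doses, ]
  expect_equal(at$m_mean, 1000 * exp(exp(phi_l[1, ]) - 0.2),
               tolerance = 1e-6)
})

test_that("matched birth and death give a flat mean curve at n0", {
  doses <- seq(-8, -5, length.out = 4)
  set.seed(2)
  phi <- matrix(rnorm(150 * 4, log(0.6), 0.1), 150, 4)
  fit <- fake_fit(phi, phi, doses)
  cv <- bd_curves(fit, n0_ref = 500, grid_size = 25)
  expect_equal(cv$m_mean[cv$z %in% doses],
               rep(500, 4), tolerance = 1e-8)
})

test_that("percentile bands match analytic quantiles for Gaussian draws", {
  doses <- c(-8, -5)
  set.seed(3)
  n <- 4000
  phi_l <- cbind(rnorm(n, 0, 0.2), rnorm(n, -0.5, 0.2))
  phi_m <- matrix(log(0.3), n, 2)
  fit <- fake_fit(phi_l, phi_m, doses)
  cv <- bd_curves(fit, n0_ref = 1000, grid_size = 2)
  # lambda at the first dose is lognormal(0, 0.2)
  expect_equal(cv$lambda_lo[1], qlnorm(0.025, 0, 0.2), tolerance = 0.03)
  expect_equal(cv$lambda_hi[1], qlnorm(0.975, 0, 0.2), tolerance = 0.03)
  expect_equal(cv$lambda_mean[1], exp(0.02), tolerance = 0.02)
})

test_that("potency summaries propagate draw uncertainty and censoring", {
  doses <- seq(-9, -4, length.out = 9)
  set.seed(4)
  n <- 500
  # declining net growth: lambda falls from 1 to 0.1, mu constant 0.3;
  # jitter the level per draw
  base <- seq(1, 0.1, length.out = 9)
  phi_l <- log(outer(exp(rnorm(n, 0, 0.05)), base))
  phi_m <- matrix(log(0.3), n, 9)
  fit <- fake_fit(phi_l, phi_m, doses)
  pot <- bd_potency(fit, n0_ref = 1000, grid_size = 60)
  gi <- pot[pot$kind == "GI50", ]
  expect_equal(gi$censor, "none")
  expect_true(gi$ci_low < gi$posterior_mean &
                gi$posterior_mean < gi$ci_high)
  expect_true(gi$ci_low < gi$estimate & gi$estimate < gi$ci_high)
  expect_equal(gi$fraction_censored, 0)
  # per-draw ordering GI50 <= TGI <= LC50 on non-increasing curves
  ok <- pot$censor == "none"
  expect_true(all(diff(pot$log10_estimate[ok]) >= 0))
  # a flat-doubling posterior censors everything
  fit2 <- fake_fit(matrix(log(0.9), 200, 9), matrix(log(0.2), 200, 9),
                   doses)
  pot2 <- bd_potency(fit2, n0_ref = 1000, grid_size = 40)
  expect_true(all(pot2$fraction_censored == 1))
  expect_true(all(is.na(pot2$posterior_mean)))
})

test_that("rate percent change follows its defining formula", {
  doses <- seq(-9, -4, length.out = 5)
  # constant posterior-mean rates: 0 percent change
  fit <- fake_fit(matrix(log(0.8), 100, 5), matrix(log(0.3), 100, 5), doses)
  rc <- bd_rate_change(fit)
  expect_equal(rc$change_pct, c(0, 0), tolerance = 1e-9)
  # doubling birth rate, tripling death rate across the range
  phi_l <- matrix(rep(log(c(0.4, 0.5, 0.6, 0.7, 0.8)), each = 100), 100, 5)
  phi_m <- matrix(rep(log(c(0.2, 0.3, 0.4, 0.5, 0.6)), each = 100), 100, 5)
  fit2 <- fake_fit(phi_l, phi_m, doses)
  rc2 <- bd_rate_change(fit2)
  expect_equal(rc2$change_pct[rc2$rate == "birth"], 100, tolerance = 1e-9)
  expect_equal(rc2$change_pct[rc2$rate == "death"], 200, tolerance = 1e-9)
})

test_that("autoplot returns ggplot objects for both panels", {
  doses <- seq(-9, -4, length.out = 5)
  fit <- fake_fit(matrix(log(0.8), 120, 5), matrix(log(0.3), 120, 5), doses)
  cv <- bd_curves(fit, n0_ref = 1000, grid_size = 20)
  expect_s3_class(autoplot(cv), "ggplot")
  expect_s3_class(autoplot(cv, which = "rates"), "ggplot")
})
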