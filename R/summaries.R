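# Smallest crossing of y(z) with a horizontal target, by linear
# interpolation on the grid. Returns list(z = crossing or NA, n = number of
# crossings, side = "below"/"above" when there is no crossing: the side of
# the target the whole curve sits on relative to the threshold direction).
first_crossing <- function(z, y, target) {
  s <- y - target
  if (s[1] == 0) {
    return(list(z = z[1], n = 1L))
  }
  hits <- which(s[-length(s)] * s[-1] <= 0 & s[-length(s)] != 0)
  if (!length(hits)) {
    return(list(z = NA_real_, n = 0L,
                side = if (all(s > 0)) "above" else "below"))
  }
  i <- hits[1]
  zc <- z[i] + (z[i + 1] - z[i]) * s[i] / (s[i] - s[i + 1])
  list(z = zc, n = length(hits))
}

# Potency concentration of one mean curve m(z) (counts) for one summary
# kind. Thresholds: GI50 - net growth halved relative to control growth
# g_control; TGI - final mean equals n0_ref; LC50 - final mean equals
# n0_ref / 2. Returns list(z, censor, n_crossings).
curve_potency <- function(z, m, n0_ref, kind, g_control) {
  target <- switch(kind,
    GI50 = {
      if (!is.finite(g_control) || g_control <= 0) {
        return(list(z = NA_real_, censor = "control_nonpositive",
                    n_crossings = 0L))
      }
      n0_ref + 0.5 * g_control
    },
    TGI = n0_ref,
    LC50 = 0.5 * n0_ref,
    stop("unknown summary kind: ", kind)
  )
  cr <- first_crossing(z, m, target)
  if (is.na(cr$z)) {
    censor <- if (identical(cr$side, "above")) "above_range" else "below_range"
    return(list(z = NA_real_, censor = censor, n_crossings = 0L))
  }
  list(z = cr$z, censor = "none", n_crossings = cr$n)
}

# Equal-quantile credible interval from order statistics: the k-th smallest
# and k-th largest draws with k = ceiling(level/2 * n).
eq_quantile_ci <- function(x, level = 0.05) {
  n <- length(x)
  k <- max(1L, ceiling(level / 2 * n))
  xs <- sort(x)
  c(xs[k], xs[n + 1L - k])
}

# Per-draw latent curves on a prediction grid: each retained draw's
# log-rate vectors are extended from the tested doses to `z_grid` by the
# GP conditional mean under that draw's hyperparameters, then
# exponentiated. Every draw therefore contributes its own smooth
# interpolant; dose-level and hyperparameter uncertainty propagate fully
# into the pointwise spread. (The conditional's own noise is not added:
# sampling it feeds a double exponential and a handful of draws with
# short length-scales would dominate every pointwise mean.)
# Returns list(z, lambda, mu) with matrices draws x grid points.
curve_draws <- function(fit, z_grid) {
  nd <- nrow(fit$phi_lambda)
  h <- fit$hypers
  lam <- matrix(NA_real_, nd, length(z_grid))
  mu <- matrix(NA_real_, nd, length(z_grid))
  for (i in seq_len(nd)) {
    lam[i, ] <- exp(gp_conditional(
      z_grid, fit$doses, fit$phi_lambda[i, ], h$alpha_lambda[i],
      h$tau2_lambda[i], h$l2_lambda[i])$mean)
    mu[i, ] <- exp(gp_conditional(
      z_grid, fit$doses, fit$phi_mu[i, ], h$alpha_mu[i],
      h$tau2_mu[i], h$l2_mu[i])$mean)
  }
  list(z = z_grid, lambda = lam, mu = mu)
}

default_grid <- function(fit, grid_size) {
  sort(unique(c(seq(min(fit$doses), max(fit$doses), length.out = grid_size),
                fit$doses)))
}

default_n0_ref <- function(fit) mean(fit$experiment$wells$n0)

# Pointwise posterior mean with a light symmetric trim (1% per tail).
# Under weak replication the posterior of the rates has a thin but
# extremely heavy tail (isolated large-turnover excursions at single
# doses); on the exp scale a handful of such draws can dominate a raw
# mean, so all pointwise curve/rate means are trimmed. Quantile-based
# intervals are unaffected.
robust_mean <- function(x) mean(x, trim = 0.01)

#' Posterior dose-response curve summaries
#'
#' For each retained posterior draw, the latent log-rate curves are extended
#' from the tested doses to a dense grid by the exact Gaussian-process
#' conditional under that draw's hyperparameters, and the expected final
#' count \eqn{m(n_0, z) = n_0 \exp(\lambda(z) - \mu(z))} is evaluated.
#' Pointwise posterior means and 95% equal-quantile credible intervals are
#' returned for the mean-count curve and for the birth and death rate
#' curves.
#'
#' @param fit A [bd_fit()] result.
#' @param n0_ref Reference initial count for the mean curve (default: the
#'   experiment's mean n0).
#' @param grid_size Number of grid points spanning the tested dose range
#'   (the tested doses themselves are always included).
#' @return A tibble of class `"bd_curves"`: columns `z`, then
#'   `mean`/`lo`/`hi` triples for `m`, `lambda` and `mu`.
#' @export
bd_curves <- function(fit, n0_ref = NULL, grid_size = 100) {
  stopifnot(inherits(fit, "bd_fit"))
  if (nrow(fit$phi_lambda) < 100) {
    warning("fewer than 100 retained draws; curve summaries will be noisy")
  }
  if (is.null(n0_ref)) n0_ref <- default_n0_ref(fit)
  zg <- default_grid(fit, grid_size)
  cd <- curve_draws(fit, zg)
  m <- n0_ref * exp(cd$lambda - cd$mu)
  summarise_mat <- function(mat, prefix) {
    ci <- apply(mat, 2, eq_quantile_ci)
    out <- tibble::tibble(apply(mat, 2, robust_mean), ci[1, ], ci[2, ])
    names(out) <- paste0(prefix, c("_mean", "_lo", "_hi"))
    out
  }
  out <- dplyr::bind_cols(
    tibble::tibble(z = zg),
    summarise_mat(m, "m"),
    summarise_mat(cd$lambda, "lambda"),
    summarise_mat(cd$mu, "mu")
  )
  class(out) <- c("bd_curves", class(out))
  attr(out, "n0_ref") <- n0_ref
  attr(out, "experiment_id") <- fit$experiment$wells$experiment_id[1]
  out
}

#' Potency summaries (GI50, TGI, LC50) with credible intervals
#'
#' Definitions, relative to a reference initial count `n0_ref` and a control
#' dose (by default the smallest tested concentration): GI50 is the smallest
#' concentration at which net population growth `m(z) - n0_ref` falls to
#' half the control's net growth; TGI the smallest concentration at which
#' the expected final count equals the initial count (zero net growth);
#' LC50 the smallest concentration at which the expected final count is
#' half the initial count.
#'
#' Each crossing is solved per posterior draw on a dense grid (monotone
#' linear interpolation between grid points; the smallest crossing is taken
#' when a wiggly curve crosses more than once, and the multiple-crossing
#' fraction is reported). Draws whose curve never reaches the threshold
#' inside the tested range are censored and excluded from the mean/CI but
#' counted in `fraction_censored`. The point `estimate` solves the same
#' crossing on the posterior-mean curve; `posterior_mean` and the 95%
#' equal-quantile interval come from the per-draw crossings.
#'
#' @inheritParams bd_curves
#' @param kinds Which summaries to compute.
#' @param control Control policy: `"min_dose"` uses the smallest tested
#'   concentration as the GI50 reference; `"fixed"` uses `control_growth`.
#' @param control_growth Net control growth (counts) when
#'   `control = "fixed"`, e.g. from dedicated untreated wells.
#' @return A tibble of class `"bd_potency"`: one row per kind with
#'   concentrations in molar (`estimate`, `posterior_mean`, `ci_low`,
#'   `ci_high`), the same on the log10 scale (`log10_*`), the censor status
#'   of the point estimate, `fraction_censored` and `fraction_multiple`.
#' @export
bd_potency <- function(fit, kinds = c("GI50", "TGI", "LC50"),
                       n0_ref = NULL, control = c("min_dose", "fixed"),
                       control_growth = NULL, grid_size = 100) {
  stopifnot(inherits(fit, "bd_fit"))
  control <- match.arg(control)
  kinds <- match.arg(kinds, several.ok = TRUE)
  if (is.null(n0_ref)) n0_ref <- default_n0_ref(fit)
  zg <- default_grid(fit, grid_size)
  cd <- curve_draws(fit, zg)
  m_draws <- n0_ref * exp(cd$lambda - cd$mu)
  m_mean <- apply(m_draws, 2, robust_mean)
  nd <- nrow(m_draws)
  purrr::map_dfr(kinds, function(kind) {
    gc_mean <- if (control == "min_dose") m_mean[1] - n0_ref else
      control_growth
    point <- curve_potency(zg, m_mean, n0_ref, kind, gc_mean)
    per_draw <- purrr::map(seq_len(nd), function(i) {
      gci <- if (control == "min_dose") m_draws[i, 1] - n0_ref else
        control_growth
      curve_potency(zg, m_draws[i, ], n0_ref, kind, gci)
    })
    zc <- purrr::map_dbl(per_draw, "z")
    cens <- purrr::map_chr(per_draw, "censor")
    multi <- purrr::map_int(per_draw, "n_crossings") > 1L
    ok <- !is.na(zc)
    if (any(ok)) {
      ci <- eq_quantile_ci(zc[ok])
      pm <- mean(zc[ok])
    } else {
      ci <- c(NA_real_, NA_real_); pm <- NA_real_
    }
    tibble::tibble(
      kind = kind,
      estimate = 10^point$z,
      posterior_mean = 10^pm,
      ci_low = 10^ci[1], ci_high = 10^ci[2],
      log10_estimate = point$z, log10_posterior_mean = pm,
      log10_ci_low = ci[1], log10_ci_high = ci[2],
      censor = point$censor,
      fraction_censored = mean(!ok),
      fraction_multiple = mean(multi[ok])
    )
  }) -> out
  class(out) <- c("bd_potency", class(out))
  attr(out, "n0_ref") <- n0_ref
  out
}

#' Percent change of the rates across the tested dose range
#'
#' The percentage change between the posterior-mean birth (and death) rate
#' at the largest and the smallest tested concentrations:
#' \eqn{100\,(\bar r(z_{max}) - \bar r(z_{min})) / \bar r(z_{min})}.
#' A compound that suppresses division and induces apoptosis shows a
#' negative birth change and a positive death change.
#'
#' @param fit A [bd_fit()] result.
#' @return A tibble with columns `rate` (`"birth"`, `"death"`) and
#'   `change_pct`.
#' @export
bd_rate_change <- function(fit) {
  stopifnot(inherits(fit, "bd_fit"))
  d <- length(fit$doses)
  lam_mean <- apply(exp(fit$phi_lambda), 2, robust_mean)
  mu_mean <- apply(exp(fit$phi_mu), 2, robust_mean)
  tibble::tibble(
    rate = c("birth", "death"),
    change_pct = c(100 * (lam_mean[d] - lam_mean[1]) / lam_mean[1],
                   100 * (mu_mean[d] - mu_mean[1]) / mu_mean[1])
  )
}

#' Write curve and potency summaries to CSV
#'
#' One curves CSV (grid, posterior mean and CI for the mean count and both
#' rates) and one summary CSV (potency rows plus the rate percent-changes),
#' mirroring the shape of a screening results table.
#'
#' @param fit A [bd_fit()] result.
#' @param dir Output directory.
#' @param stem File-name stem (default the experiment id).
#' @inheritParams bd_curves
#' @return Invisibly, the paths written.
#' @export
write_summaries <- function(fit, dir, stem = NULL, n0_ref = NULL,
                            grid_size = 100) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(stem)) stem <- fit$experiment$wells$experiment_id[1]
  curves <- bd_curves(fit, n0_ref = n0_ref, grid_size = grid_size)
  pot <- bd_potency(fit, n0_ref = n0_ref, grid_size = grid_size)
  rc <- bd_rate_change(fit)
  curves_path <- file.path(dir, paste0(stem, "_curves.csv"))
  summary_path <- file.path(dir, paste0(stem, "_summary.csv"))
  readr::write_csv(curves, curves_path, progress = FALSE)
  summary_tbl <- dplyr::bind_rows(
    dplyr::mutate(pot, statistic = .data$kind, .before = 1),
    tibble::tibble(statistic = paste0("delta_", rc$rate, "_pct"),
                   estimate = rc$change_pct)
  )
  readr::write_csv(summary_tbl, summary_path, progress = FALSE)
  invisible(c(curves = curves_path, summary = summary_path))
}
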