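#' @export
print.bd_fit <- function(x, ...) {
  cat("<bd_fit> ", x$experiment$wells$experiment_id[1], "\n", sep = "")
  cat("  ", nrow(x$phi_lambda), " retained draws over ",
      length(x$doses), " doses (n_iter = ", x$config$n_iter,
      ", burn-in = ", x$config$n_burn, ", thin = ", x$config$thin, ")\n",
      sep = "")
  ar <- unlist(x$acceptance)
  cat("  acceptance: ",
      paste(sprintf("%s %.2f", names(ar), ar), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Tidy posterior summaries of a fit
#'
#' With `pars = "hypers"`, one row per hyperparameter (GP means, kernel
#' variances, squared length-scales, noise mean and variance) with
#' posterior mean, standard deviation and 95% equal-quantile interval.
#' With `pars = "rates"`, one row per tested dose and rate curve (birth,
#' death) summarising the per-cell rate itself (exponentiated latent).
#'
#' @param x A [bd_fit()] result.
#' @param pars `"hypers"` or `"rates"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.bd_fit <- function(x, pars = c("hypers", "rates"), ...) {
  pars <- match.arg(pars)
  if (pars == "hypers") {
    purrr::map_dfr(names(x$hypers), function(p) {
      v <- x$hypers[[p]]
      ci <- eq_quantile_ci(v)
      tibble::tibble(term = p, estimate = mean(v), std.error = sd(v),
                     conf.low = ci[1], conf.high = ci[2])
    })
  } else {
    purrr::map_dfr(seq_along(x$doses), function(i) {
      purrr::map_dfr(c(birth = "lambda", death = "mu"), function(which_r) {
        v <- exp(if (which_r == "lambda") x$phi_lambda[, i] else
          x$phi_mu[, i])
        ci <- eq_quantile_ci(v)
        tibble::tibble(z_log10M = x$doses[i],
                       rate = if (which_r == "lambda") "birth" else "death",
                       estimate = robust_mean(v), std.error = sd(v),
                       conf.low = ci[1], conf.high = ci[2])
      })
    })
  }
}

#' One-row fit overview
#'
#' @param x A [bd_fit()] result.
#' @param ... Unused.
#' @return A one-row tibble: draw count, mean log-posterior, worst split
#'   R-hat, smallest effective sample size, and latent-block acceptance
#'   rates.
#' @export
glance.bd_fit <- function(x, ...) {
  diag <- suppressWarnings(bd_diagnostics(x))
  tibble::tibble(
    n_draws = nrow(x$phi_lambda),
    n_doses = length(x$doses),
    mean_logpost = mean(x$logpost),
    max_rhat = suppressWarnings(max(diag$rhat, na.rm = TRUE)),
    min_ess = suppressWarnings(min(diag$ess, na.rm = TRUE)),
    accept_phi_lambda = x$acceptance$phi_l,
    accept_phi_mu = x$acceptance$phi_m
  )
}

#' @export
tidy.bd_sigmoid <- function(x, ...) {
  tibble::tibble(term = names(x$coef), estimate = unname(x$coef))
}

#' @export
glance.bd_sigmoid <- function(x, ...) {
  tibble::tibble(family = x$family, sse = x$sse, sigma2 = x$sigma2,
                 converged = x$converged, nobs = nrow(x$wells))
}

#' Plot posterior dose-response curves
#'
#' The expected final count against log10 concentration with its 95%
#' credible ribbon (`which = "mean"`), or the birth and death rate curves
#' in facets (`which = "rates"`).
#'
#' @param object A [bd_curves()] tibble.
#' @param which `"mean"` or `"rates"`.
#' @param data Optional wells tibble overlaid as points on the mean panel.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bd_curves <- function(object, which = c("mean", "rates"),
                               data = NULL, ...) {
  which <- match.arg(which)
  if (which == "mean") {
    p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$z)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$m_lo,
                                        ymax = .data$m_hi),
                           fill = "steelblue", alpha = 0.3) +
      ggplot2::geom_line(ggplot2::aes(y = .data$m_mean),
                         colour = "steelblue") +
      ggplot2::labs(x = "log10 concentration (M)",
                    y = "expected final count",
                    title = attr(object, "experiment_id"))
    if (!is.null(data)) {
      p <- p + ggplot2::geom_point(
        data = data, ggplot2::aes(x = .data$z_log10M, y = .data$count))
    }
    p
  } else {
    long <- tidyr::pivot_longer(
      dplyr::select(object, "z", dplyr::starts_with("lambda"),
                    dplyr::starts_with("mu")),
      -"z",
      names_to = c("rate", "stat"), names_pattern = "(lambda|mu)_(.*)")
    long <- tidyr::pivot_wider(long, names_from = "stat",
                               values_from = "value")
    long$rate <- ifelse(long$rate == "lambda", "birth rate",
                        "death rate")
    ggplot2::ggplot(long, ggplot2::aes(x = .data$z)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                           fill = "firebrick", alpha = 0.25) +
      ggplot2::geom_line(ggplot2::aes(y = .data$mean), colour = "firebrick") +
      ggplot2::facet_wrap(~rate, scales = "free_y") +
      ggplot2::labs(x = "log10 concentration (M)", y = "per-cell rate")
  }
}

#' @rdname autoplot.bd_curves
#' @export
autoplot.bd_fit <- function(object, which = c("mean", "rates"), ...) {
  curves <- bd_curves(object)
  autoplot(curves, which = which, data = object$experiment$wells, ...)
}
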