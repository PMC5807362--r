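sigmoid_fun <- function(family) {
  switch(family,
    gompertz = function(z, p) p[1] + p[2] * exp(-exp(p[3] + p[4] * z)),
    logistic = function(z, p) p[1] + p[2] / (1 + exp((z - p[3]) / p[4])),
    stop("unknown sigmoid family: ", family)
  )
}

sigmoid_starts <- function(family, z, y, n_starts) {
  top <- max(y); bottom <- min(y); span <- max(top - bottom, 1e-8)
  z_mid <- stats::median(z); z_range <- diff(range(z))
  base <- if (family == "gompertz") {
    expand.grid(p1 = c(bottom, bottom - 0.1 * span),
                p2 = c(span, 1.5 * span),
                p4 = c(0.5, 1, 2, 4) / max(z_range / 5, 0.2))
  } else {
    expand.grid(p1 = c(bottom, bottom - 0.1 * span),
                p2 = c(span, 1.5 * span),
                p4 = c(0.1, 0.3, 0.8, 2) * max(z_range / 5, 0.2))
  }
  starts <- lapply(seq_len(nrow(base)), function(i) {
    r <- base[i, ]
    if (family == "gompertz") {
      c(r$p1, r$p2, -r$p4 * z_mid, r$p4)
    } else {
      c(r$p1, r$p2, z_mid, r$p4)
    }
  })
  # jittered extras keep multi-start honest on awkward data
  while (length(starts) < n_starts) {
    starts[[length(starts) + 1L]] <-
      starts[[sample.int(nrow(base), 1)]] * exp(rnorm(4, 0, 0.2))
  }
  starts
}

#' Conventional sigmoid dose-response fits
#'
#' Nonlinear least-squares fits of the two classical parametric growth
#' curves to well counts against log10 concentration:
#' Gompertz \eqn{g(z) = \phi_0 + \phi_1 \exp(-\exp(\phi_2 + \phi_3 z))} and
#' logistic \eqn{g(z) = \psi_0 + \psi_1 / (1 + \exp((z-\psi_2)/\psi_3))}.
#' These single-curve fits describe only the combined effect of birth and
#' death and give point estimates without uncertainty; they are provided as
#' the standard baseline against the birth-death model. Fitting is
#' Levenberg-Marquardt with at least ten data-driven starting points; the
#' best sum-of-squares solution wins and the convergence flag is honest
#' (all starts failing yields a non-converged result, not an error).
#'
#' @param experiment A [bd_experiment()] or a data frame with columns
#'   `z_log10M` and `count`.
#' @param family `"gompertz"` or `"logistic"`.
#' @param n_starts Number of starting points (>= 10 enforced).
#' @param seed Optional seed for the jittered extra starts.
#' @return An object of class `"bd_sigmoid"`: coefficients, `sse`,
#'   `sigma2` (residual variance), `converged`, the family and the data.
#' @examples
#' sim <- simulate_experiment("both", seed = 1)
#' fit <- fit_sigmoid(sim$experiment, "gompertz")
#' glance(fit)
#' @export
fit_sigmoid <- function(experiment, family = c("gompertz", "logistic"),
                        n_starts = 10, seed = NULL) {
  family <- match.arg(family)
  if (!is.null(seed)) set.seed(seed)
  wells <- if (inherits(experiment, "bd_experiment")) experiment$wells else
    tibble::as_tibble(experiment)
  z <- wells$z_log10M; y <- wells$count
  if (length(unique(z)) < 5L) {
    stop("need >= 5 distinct doses to fit a 4-parameter sigmoid")
  }
  n_starts <- max(n_starts, 10L)
  f <- sigmoid_fun(family)
  starts <- sigmoid_starts(family, z, y, n_starts)
  best <- NULL
  for (p0 in starts) {
    fitted <- tryCatch(suppressWarnings(minpack.lm::nlsLM(
      y ~ f(z, c(p1, p2, p3, p4)),
      start = list(p1 = p0[1], p2 = p0[2], p3 = p0[3], p4 = p0[4]),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )), error = function(e) NULL)
    if (is.null(fitted)) next
    sse <- sum(stats::residuals(fitted)^2)
    if (is.null(best) || sse < best$sse) {
      best <- list(coef = stats::coef(fitted), sse = sse)
    }
  }
  par_names <- if (family == "gompertz") paste0("phi", 0:3) else
    paste0("psi", 0:3)
  if (is.null(best)) {
    out <- list(family = family, coef = setNames(rep(NA_real_, 4), par_names),
                sse = NA_real_, sigma2 = NA_real_, converged = FALSE,
                wells = wells)
  } else {
    out <- list(family = family, coef = setNames(unname(best$coef), par_names),
                sse = best$sse,
                sigma2 = best$sse / max(length(y) - 4, 1),
                converged = TRUE, wells = wells)
  }
  structure(out, class = "bd_sigmoid")
}

#' Predicted counts from a sigmoid fit
#'
#' @param object A [fit_sigmoid()] result.
#' @param z Log10 concentrations at which to evaluate the fitted curve
#'   (default: the fitted data's doses).
#' @param ... Unused.
#' @return Numeric vector of predicted counts.
#' @export
predict.bd_sigmoid <- function(object, z = NULL, ...) {
  if (!object$converged) stop("sigmoid fit did not converge")
  if (is.null(z)) z <- object$wells$z_log10M
  sigmoid_fun(object$family)(z, unname(object$coef))
}

#' Point-estimate potency from a sigmoid fit
#'
#' Solves the same GI50/TGI/LC50 threshold definitions as [bd_potency()] on
#' the fitted parametric curve. These are point estimates only: the
#' parametric route carries no posterior, hence no credible interval.
#'
#' @param fit A converged [fit_sigmoid()] result.
#' @param kinds Which summaries to compute.
#' @param n0_ref Reference initial count (default: mean `n0` of the fitted
#'   wells if present, else the fitted top plateau).
#' @param grid_size Resolution of the crossing grid over the tested range.
#' @return A tibble with columns `kind`, `estimate` (M), `log10_estimate`,
#'   `censor`.
#' @export
sigmoid_potency <- function(fit, kinds = c("GI50", "TGI", "LC50"),
                            n0_ref = NULL, grid_size = 200) {
  stopifnot(inherits(fit, "bd_sigmoid"))
  if (!fit$converged) stop("sigmoid fit did not converge")
  kinds <- match.arg(kinds, several.ok = TRUE)
  if (is.null(n0_ref)) {
    n0_ref <- if ("n0" %in% names(fit$wells)) mean(fit$wells$n0) else
      max(predict(fit))
  }
  zg <- seq(min(fit$wells$z_log10M), max(fit$wells$z_log10M),
            length.out = grid_size)
  m <- predict(fit, zg)
  purrr::map_dfr(kinds, function(kind) {
    cr <- curve_potency(zg, m, n0_ref, kind, g_control = m[1] - n0_ref)
    tibble::tibble(kind = kind, estimate = 10^cr$z, log10_estimate = cr$z,
                   censor = cr$censor)
  })
}
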