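#' Assemble a chemo-sensitivity experiment
#'
#' Bundles the well-level measurements of one compound-by-cell-line
#' experiment with its compound-free background wells. Doses are log10 molar
#' concentrations; replicate wells simply repeat a dose. Initial counts
#' `n0` are treated as known and may differ between wells. At least two
#' distinct doses and at least two background measurements are required (the
#' background pair identifies the noise mean and variance).
#'
#' @param wells Data frame with columns `experiment_id`, `z_log10M`, `n0`,
#'   `count` (extra columns are kept).
#' @param background Numeric vector of background measurements, or a data
#'   frame with a `noise` column.
#' @param metadata Optional named list (cell line, compound, follow-up time,
#'   units, ...).
#' @return An object of class `"bd_experiment"`: a list with elements
#'   `wells` (tibble), `background` (numeric), `metadata` (list).
#' @examples
#' wells <- tibble::tibble(
#'   experiment_id = "demo", z_log10M = rep(c(-8, -6), each = 2),
#'   n0 = 1000, count = c(1810, 1792, 905, 930)
#' )
#' bd_experiment(wells, background = c(18, 22))
#' @export
bd_experiment <- function(wells, background, metadata = list()) {
  wells <- tibble::as_tibble(wells)
  required <- c("experiment_id", "z_log10M", "n0", "count")
  missing_cols <- setdiff(required, names(wells))
  if (length(missing_cols)) {
    stop("wells is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.data.frame(background)) {
    if (!"noise" %in% names(background)) {
      stop("background data frame must have a 'noise' column")
    }
    background <- background$noise
  }
  background <- as.numeric(background)
  bad <- which(!stats::complete.cases(wells[required]))
  if (length(bad)) {
    stop("wells has missing values in row(s): ", paste(bad, collapse = ", "))
  }
  if (!is.numeric(wells$z_log10M) || !all(is.finite(wells$z_log10M))) {
    stop("z_log10M must be finite numeric")
  }
  if (!is.numeric(wells$n0) || any(wells$n0 <= 0)) {
    stop("all initial counts n0 must be positive")
  }
  if (!is.numeric(wells$count)) stop("count must be numeric")
  if (length(unique(wells$z_log10M)) < 2L) {
    stop("need at least 2 distinct doses")
  }
  if (length(background) < 2L || any(!is.finite(background))) {
    stop("need at least 2 finite background measurements to identify ",
         "the noise mean and variance (theta, sigma^2)")
  }
  structure(list(wells = wells, background = background, metadata = metadata),
            class = "bd_experiment")
}

#' @export
print.bd_experiment <- function(x, ...) {
  doses <- sort(unique(x$wells$z_log10M))
  cat("<bd_experiment> ", x$wells$experiment_id[1], "\n", sep = "")
  cat("  ", nrow(x$wells), " wells over ", length(doses),
      " doses (log10 M in [", min(doses), ", ", max(doses), "]), ",
      length(x$background), " background wells\n", sep = "")
  invisible(x)
}

#' Read an experiment from CSV files
#'
#' The counts file must have header columns `experiment_id`, `z_log10M`,
#' `n0`, `count`; the background file a column `noise`. Both are plain
#' UTF-8, comma-delimited CSV with `.` decimals. Rows with missing or
#' non-numeric values are rejected with their line numbers.
#'
#' @param counts_path Path to the well-count CSV.
#' @param background_path Path to the background CSV.
#' @param metadata Optional named list carried into the experiment.
#' @return A [bd_experiment()] object.
#' @export
read_experiment <- function(counts_path, background_path, metadata = list()) {
  wells <- readr::read_csv(counts_path, show_col_types = FALSE,
                           progress = FALSE)
  required <- c("experiment_id", "z_log10M", "n0", "count")
  missing_cols <- setdiff(required, names(wells))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing column(s) %s", counts_path,
                 paste(missing_cols, collapse = ", ")))
  }
  for (col in c("z_log10M", "n0", "count")) {
    v <- wells[[col]]
    if (!is.numeric(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(parsed) & !is.na(v))
      stop(sprintf("%s: column '%s' is not numeric (line %s)", counts_path,
                   col, paste(bad + 1L, collapse = ", ")))
    }
    bad <- which(is.na(v))
    if (length(bad)) {
      stop(sprintf("%s: missing value in column '%s' (line %s)", counts_path,
                   col, paste(bad + 1L, collapse = ", ")))
    }
  }
  bg <- readr::read_csv(background_path, show_col_types = FALSE,
                        progress = FALSE)
  if (!"noise" %in% names(bg)) {
    stop(sprintf("%s: missing column 'noise'", background_path))
  }
  bd_experiment(wells, bg, metadata = metadata)
}

#' Write an experiment to CSV files
#'
#' Inverse of [read_experiment()]; the round trip preserves all values.
#'
#' @param experiment A [bd_experiment()] object.
#' @param counts_path,background_path Output paths.
#' @return The experiment, invisibly.
#' @export
write_experiment <- function(experiment, counts_path, background_path) {
  stopifnot(inherits(experiment, "bd_experiment"))
  readr::write_csv(experiment$wells, counts_path, progress = FALSE)
  readr::write_csv(tibble::tibble(noise = experiment$background),
                   background_path, progress = FALSE)
  invisible(experiment)
}

#' Write fit outputs and a run manifest
#'
#' Serialises retained posterior draws to a flat CSV (one row per retained
#' iteration, hyperparameters plus per-dose log-rates), and a JSON manifest
#' recording the configuration, seed, acceptance rates and convergence
#' diagnostics, so a run is fully reproducible from its outputs.
#'
#' @param fit A [bd_fit()] result.
#' @param dir Output directory (created if needed).
#' @param stem File-name stem (default the experiment id).
#' @return Invisibly, the paths written.
#' @export
write_fit <- function(fit, dir, stem = NULL) {
  stopifnot(inherits(fit, "bd_fit"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(stem)) stem <- fit$experiment$wells$experiment_id[1]
  d <- length(fit$doses)
  draws <- tibble::as_tibble(cbind(
    fit$hypers,
    setNames(as.data.frame(fit$phi_lambda), paste0("phi_lambda_", seq_len(d))),
    setNames(as.data.frame(fit$phi_mu), paste0("phi_mu_", seq_len(d)))
  ))
  draws_path <- file.path(dir, paste0(stem, "_draws.csv"))
  readr::write_csv(draws, draws_path, progress = FALSE)
  manifest <- list(
    package = "bdrates",
    r_version = as.character(getRversion()),
    experiment_id = stem,
    doses_log10M = fit$doses,
    config = fit$config,
    acceptance = fit$acceptance,
    diagnostics = tryCatch(as.list(glance(fit)), error = function(e) NULL)
  )
  manifest_path <- file.path(dir, paste0(stem, "_manifest.json"))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(draws = draws_path, manifest = manifest_path))
}
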