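#' Network-recovery metrics
#'
#' Compares an estimated network to its generating truth over the
#' `p(p-1)/2` upper-triangle entries: `error` is the mean absolute weight
#' difference; `sensitivity` the share of true edges estimated nonzero;
#' `specificity` the share of true non-edges estimated zero; `correlation`
#' the Pearson correlation between the true and estimated weight vectors.
#' When either weight vector is constant (e.g. an empty estimate) the
#' correlation is undefined: it is recorded as 0 with
#' `correlation_defined = FALSE`. Sensitivity of a truth with zero edges
#' and specificity of a saturated truth are `NA`.
#'
#' @param truth a `true_network_spec`.
#' @param estimate a `ggm_network` with the same labels.
#' @return List: `error`, `sensitivity`, `specificity`, `correlation`,
#'   `correlation_defined`.
#' @export
recovery_metrics <- function(truth, estimate) {
  if (!identical(truth$labels, estimate$labels)) {
    stopf("truth and estimate have different labels")
  }
  wt <- upper_vec(truth$partial_corr)
  we <- upper_vec(estimate$weights)
  true_edge <- wt != 0
  est_edge <- we != 0

  sens <- if (any(true_edge)) mean(est_edge[true_edge]) else NA_real_
  spec <- if (any(!true_edge)) mean(!est_edge[!true_edge]) else NA_real_
  corr_defined <- stats::sd(wt) > 0 && stats::sd(we) > 0
  corr <- if (corr_defined) stats::cor(wt, we) else 0

  list(error = mean(abs(we - wt)),
       sensitivity = sens,
       specificity = spec,
       correlation = corr,
       correlation_defined = corr_defined)
}

#' Configuration for the sample-size simulation study
#'
#' The emulated study crossed sample size (100, 250, 350, 500, 750, 1000),
#' variable count (5, 10, 15, 20, 25) and network density (low, medium,
#' high) with 100 replicates per cell. Densities map to edge probabilities
#' 0.1 / 0.3 / 0.5; true networks come from the diagonal-dominance
#' construction of [generate_true_network()] (raw weights `U(0.5, 1)`
#' signed), under which denser networks carry systematically weaker
#' partial correlations.
#'
#' @param sample_sizes integer vector.
#' @param variable_counts integer vector.
#' @param densities character subset of `c("low", "medium", "high")`.
#' @param replicates replicates per grid cell (study value: 100).
#' @param seed master seed.
#' @param density_map named numeric mapping density labels to edge
#'   probabilities.
#' @param weight_range absolute edge-weight range for the true networks.
#' @param folds CV folds for the estimator.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(sample_sizes = c(100, 250, 350, 500, 750, 1000),
                              variable_counts = c(5, 10, 15, 20, 25),
                              densities = c("low", "medium", "high"),
                              replicates = 100,
                              seed = 1L,
                              density_map = c(low = 0.1, medium = 0.3,
                                              high = 0.5),
                              weight_range = c(0.5, 1),
                              folds = 10) {
  stopifnot(all(sample_sizes > 0), all(variable_counts > 0), replicates >= 1,
            all(densities %in% names(density_map)))
  structure(list(sample_sizes = sample_sizes,
                 variable_counts = variable_counts,
                 densities = densities, replicates = replicates, seed = seed,
                 density_map = density_map, weight_range = weight_range,
                 folds = folds),
            class = "simulation_config")
}

#' Run the network-recovery simulation study
#'
#' For every grid cell (n, p, density) and replicate: generate a true
#' network, sample n Gaussian rows from it, estimate the network with the
#' full nodewise-LASSO pipeline, and score recovery with
#' [recovery_metrics()]. Replicate seeds are derived deterministically from
#' the master seed and the cell coordinates, so any subset of the grid
#' reproduces identically. Replicates whose estimation fails are excluded
#' from aggregation and counted; replicates with undefined weight
#' correlation contribute to all means except the correlation.
#'
#' @param config a [simulation_config()].
#' @param verbose log each finished cell (default TRUE).
#' @return A `simulation_result`: data frame `cells` with one row per grid
#'   cell carrying mean and standard deviation of estimation error,
#'   sensitivity, specificity and weight correlation over replicates,
#'   together with `n_failed` and `n_corr_undefined`; plus the config.
#' @export
run_simulation <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "simulation_config"))
  grid <- expand.grid(n = config$sample_sizes, p = config$variable_counts,
                      density = config$densities,
                      stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    n <- grid$n[g]; p <- grid$p[g]; dens <- grid$density[g]
    d_num <- config$density_map[[dens]]
    met <- matrix(NA_real_, config$replicates, 4,
                  dimnames = list(NULL, c("error", "sensitivity",
                                          "specificity", "correlation")))
    corr_def <- logical(config$replicates)
    failed <- 0L
    for (r in seq_len(config$replicates)) {
      cell_seed <- derive_seed(config$seed, n, p, match(dens, names(
        config$density_map)), r)
      res <- tryCatch({
        truth <- generate_true_network(p, d_num, config$weight_range,
                                       seed = cell_seed,
                                       density_label = dens)
        x <- sample_gaussian(truth, n, seed = derive_seed(cell_seed, 2))
        est <- estimate_network(x, folds = config$folds,
                                seed = derive_seed(cell_seed, 3))
        recovery_metrics(truth, est)
      }, error = function(e) NULL)
      if (is.null(res)) { failed <- failed + 1L; next }
      met[r, ] <- c(res$error, res$sensitivity, res$specificity,
                    res$correlation)
      corr_def[r] <- res$correlation_defined
    }
    ok <- !is.na(met[, "error"])
    corr_vals <- met[ok & corr_def, "correlation"]
    rows[[g]] <- data.frame(
      n = n, p = p, density = dens,
      error_mean = mean(met[ok, "error"]),
      error_sd = stats::sd(met[ok, "error"]),
      sensitivity_mean = mean(met[ok, "sensitivity"], na.rm = TRUE),
      sensitivity_sd = stats::sd(met[ok, "sensitivity"], na.rm = TRUE),
      specificity_mean = mean(met[ok, "specificity"], na.rm = TRUE),
      specificity_sd = stats::sd(met[ok, "specificity"], na.rm = TRUE),
      correlation_mean = if (length(corr_vals)) mean(corr_vals) else NA_real_,
      correlation_sd = if (length(corr_vals) > 1) stats::sd(corr_vals)
                       else NA_real_,
      n_replicates = sum(ok),
      n_failed = failed,
      n_corr_undefined = sum(ok & !corr_def)
    )
    if (verbose) {
      message(sprintf(
        "cell n=%d p=%d %s: sens %.3f spec %.3f corr %.3f err %.4f",
        n, p, dens, rows[[g]]$sensitivity_mean, rows[[g]]$specificity_mean,
        rows[[g]]$correlation_mean, rows[[g]]$error_mean))
    }
  }
  structure(list(cells = do.call(rbind, rows), config = config),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("Simulation result: %d grid cells, %d replicates each\n",
              nrow(x$cells), x$config$replicates))
  print(x$cells[, c("n", "p", "density", "error_mean", "sensitivity_mean",
                    "specificity_mean", "correlation_mean")],
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write a simulation result as tidy CSV (one row per cell x metric) or JSON
#'
#' @param result a `simulation_result`.
#' @param path file path (`.csv` or `.json` by extension).
#' @return `path`, invisibly.
#' @export
write_simulation_result <- function(result, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(cells = result$cells,
                              config = unclass(result$config)),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    cells <- result$cells
    metrics <- c("error", "sensitivity", "specificity", "correlation")
    tidy <- do.call(rbind, lapply(metrics, function(m) {
      data.frame(n = cells$n, p = cells$p, density = cells$density,
                 metric = m, mean = cells[[paste0(m, "_mean")]],
                 sd = cells[[paste0(m, "_sd")]],
                 n_replicates = cells$n_replicates)
    }))
    utils::write.csv(tidy, path, row.names = FALSE)
  }
  invisible(path)
}

#' Plot simulation metric curves against sample size
#'
#' One panel per metric, one line per density, faceted over variable
#' counts. Requires ggplot2.
#'
#' @param result a `simulation_result`.
#' @param metric one of `"sensitivity"`, `"specificity"`, `"correlation"`,
#'   `"error"`.
#' @return A ggplot object.
#' @export
plot_simulation <- function(result, metric = "sensitivity") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stopf("plot_simulation requires ggplot2")
  }
  cells <- result$cells
  col <- paste0(metric, "_mean")
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$n, y = .data[[col]],
                                      colour = .data$density)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~p, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "sample size", y = metric) +
    ggplot2::theme_minimal()
}
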