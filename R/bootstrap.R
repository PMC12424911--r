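#' Bootstrap edge stability
#'
#' Nonparametric bootstrap of the full estimation pipeline: each replicate
#' resamples `n` rows with replacement and re-runs [estimate_network()]
#' with fresh CV folds drawn from the replicate's own seed (derived by
#' counter from the master seed, so replicates are independent and the
#' result does not depend on execution order). Per edge it accumulates the
#' inclusion proportion (share of replicates in which the edge is nonzero)
#' and empirical (inverse-ECDF) 2.5% and 97.5% quantiles of the bootstrap
#' edge weights.
#'
#' Replicates whose resample makes estimation fail (e.g. a constant column)
#' are redrawn; the redraw count is reported, and the run aborts if redraws
#' exceed `B`.
#'
#' @param matrix numeric matrix valid for [estimate_network()].
#' @param B number of bootstrap replicates (>= 1); the emulated study used
#'   5000.
#' @param seed master seed.
#' @param folds CV folds passed through to the estimator.
#' @param verbose log progress every 100 replicates (default TRUE).
#' @return A `bootstrap_summary`: data frame `edges` (edge,
#'   `inclusion_proportion`, `q_low`, `q_high`, `interval_width`), plus
#'   `labels`, `B`, `seed`, `redraws`, and the `boot_weights` matrix
#'   (B x edges) of replicate edge weights.
#' @export
bootstrap_network <- function(matrix, B = 5000, seed = 1L, folds = 10,
                              verbose = TRUE) {
  if (B < 1) stopf("B must be >= 1")
  x <- as.matrix(matrix)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x)
  p <- ncol(x)
  labels <- colnames(x) %||% paste0("V", seq_len(p))
  en <- edge_names(labels)
  weights <- matrix(NA_real_, B, length(en), dimnames = list(NULL, en))

  redraws <- 0L
  counter <- 0L
  for (b in seq_len(B)) {
    repeat {
      counter <- counter + 1L
      rep_seed <- derive_seed(seed, 500, counter)
      idx <- local_seed(rep_seed, sample.int(n, n, replace = TRUE))
      net <- tryCatch(
        estimate_network(x[idx, , drop = FALSE], folds = folds,
                         seed = derive_seed(rep_seed, 1)),
        error = function(e) NULL)
      if (!is.null(net)) break
      redraws <- redraws + 1L
      if (redraws > B) stopf("bootstrap aborted: redraws exceeded B = %d", B)
    }
    weights[b, ] <- upper_vec(net$weights)
    if (verbose && b %% 100 == 0) {
      message(sprintf("bootstrap replicate %d/%d", b, B))
    }
  }

  q <- apply(weights, 2, stats::quantile, probs = c(0.025, 0.975),
             type = 1, names = FALSE)
  edges <- data.frame(
    edge = en,
    inclusion_proportion = colMeans(weights != 0),
    q_low = q[1, ],
    q_high = q[2, ],
    row.names = NULL
  )
  edges$interval_width <- edges$q_high - edges$q_low
  structure(list(edges = edges, labels = labels, B = B, seed = seed,
                 redraws = redraws, boot_weights = weights),
            class = "bootstrap_summary")
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat(sprintf("Bootstrap summary: B = %d (%d redraws)\n", x$B, x$redraws))
  top <- x$edges[order(-x$edges$inclusion_proportion), ]
  print(utils::head(top[, c("edge", "inclusion_proportion", "q_low",
                            "q_high")], 8), row.names = FALSE)
  invisible(x)
}

#' Write / read a bootstrap summary
#'
#' TSV carries the per-edge table (`edge`, `inclusion_proportion`, `q_low`,
#' `q_high`, `interval_width`); JSON additionally carries B, seed and the
#' redraw count (not the raw replicate weights).
#'
#' @param summary a `bootstrap_summary`.
#' @param path file path (`.tsv` or `.json` by extension).
#' @return `write_bootstrap_summary` returns `path` invisibly;
#'   `read_bootstrap_summary` returns a `bootstrap_summary` (without raw
#'   replicate weights).
#' @export
write_bootstrap_summary <- function(summary, path) {
  if (grepl("\\.tsv$", path)) {
    utils::write.table(summary$edges, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  } else {
    jsonlite::write_json(list(edges = summary$edges, labels = summary$labels,
                              B = summary$B, seed = summary$seed,
                              redraws = summary$redraws),
                         path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_bootstrap_summary
#' @export
read_bootstrap_summary <- function(path) {
  if (grepl("\\.tsv$", path)) {
    edges <- utils::read.table(path, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
    obj <- list(edges = edges, labels = NULL, B = NA_integer_,
                seed = NA_integer_, redraws = NA_integer_)
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    obj$edges <- as.data.frame(obj$edges)
  }
  structure(list(edges = obj$edges, labels = obj$labels, B = obj$B,
                 seed = obj$seed, redraws = obj$redraws,
                 boot_weights = NULL),
            class = "bootstrap_summary")
}
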