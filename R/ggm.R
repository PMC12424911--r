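#' Nodewise LASSO regression for one node
#'
#' Regresses the node on all other columns with an L1 penalty. The penalty
#' weight is selected by k-fold cross-validation, minimizing mean squared
#' error over a logarithmic grid (ties resolve to the larger penalty, i.e.
#' the sparser model); fold assignment is drawn deterministically from
#' `seed`. Returns the coefficients at the selected penalty.
#'
#' @param matrix standardized complete numeric matrix.
#' @param node column index of the response.
#' @param folds number of CV folds (default 10); requires `n >= folds >= 2`.
#' @param seed integer seed for the fold assignment.
#' @param penalty_multiplier multiplier applied to the CV-selected penalty
#'   before extracting coefficients (default 1); values above 1 give a
#'   sparser fit than the CV optimum.
#' @return List with `coef` (named vector over the other columns) and
#'   `lambda` (the selected penalty weight, after multiplication).
#' @export
nodewise_lasso <- function(matrix, node, folds = 10, seed = 1L,
                           penalty_multiplier = 1) {
  x <- as.matrix(matrix)
  if (anyNA(x)) stopf("nodewise_lasso requires complete data")
  n <- nrow(x)
  if (folds < 2 || n < folds) stopf("need n >= folds >= 2 (n=%d, folds=%d)",
                                    n, folds)
  y <- x[, node]
  xp <- x[, -node, drop = FALSE]
  foldid <- local_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  # tight convergence so the fit is invariant to predictor ordering
  cv <- glmnet::cv.glmnet(xp, y, foldid = foldid, standardize = FALSE,
                          intercept = TRUE, thresh = 1e-12)
  lam <- cv$lambda.min * penalty_multiplier
  b <- as.vector(stats::coef(cv, s = lam, exact = TRUE, x = xp, y = y,
                             thresh = 1e-12))[-1]
  names(b) <- colnames(xp)
  list(coef = b, lambda = lam)
}

#' Loh-Wainwright style coefficient thresholding
#'
#' Zeroes every coefficient with absolute value strictly below
#' `tau = c * sqrt(log(p) / n)`; a coefficient exactly at `tau` is
#' retained. [estimate_network()] supplies the constant `c` per node: by
#' default the L2 norm of the node's selected coefficient vector (the
#' convention of the nodewise-estimation software family this pipeline
#' follows), alternatively the CV-selected penalty weight.
#'
#' @param coefficients numeric vector of nodewise coefficients.
#' @param n sample size.
#' @param p total number of variables in the network.
#' @param c threshold constant.
#' @return The sparsified coefficient vector.
#' @export
threshold_coefficients <- function(coefficients, n, p, c) {
  tau <- c * sqrt(log(p) / n)
  coefficients[abs(coefficients) < tau] <- 0
  coefficients
}

#' Combine nodewise regressions into an undirected network
#'
#' Edge (i, j) is present iff both regression coefficients beta_ij and
#' beta_ji are nonzero and share sign (the AND rule); its weight is
#' `sign(beta_ij) * sqrt(beta_ij * beta_ji)`, the signed geometric mean,
#' which on standardized data approximates the partial correlation. A pair
#' with both coefficients nonzero but of conflicting sign is set to zero
#' and recorded as a warning on the returned network (not an error).
#'
#' @param betas p x p matrix; row i holds the (thresholded) coefficients
#'   from regressing node i on the others (diagonal ignored).
#' @param labels node names.
#' @param settings list stored on the network (folds, threshold rule,
#'   symmetrization rule, seed).
#' @return A `ggm_network`: `labels`, symmetric `weights` with zero
#'   diagonal, `edge_count`, `settings`, `warnings`.
#' @export
symmetrize <- function(betas, labels = NULL,
                       settings = list(symmetrization = "AND-geometric-mean")) {
  p <- nrow(betas)
  labels <- labels %||% colnames(betas) %||% paste0("V", seq_len(p))
  w <- matrix(0, p, p, dimnames = list(labels, labels))
  warnings <- character()
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      bij <- betas[i, j]; bji <- betas[j, i]
      if (bij != 0 && bji != 0) {
        if (sign(bij) != sign(bji)) {
          warnings <- c(warnings, sprintf(
            "conflicting signs for edge %s--%s (%.4g vs %.4g); edge dropped",
            labels[i], labels[j], bij, bji))
        } else {
          w[i, j] <- w[j, i] <- sign(bij) * sqrt(bij * bji)
        }
      }
    }
  }
  new_ggm_network(labels, w, settings, warnings)
}

new_ggm_network <- function(labels, weights, settings, warnings = character(),
                            betas = NULL) {
  structure(list(
    labels = labels,
    weights = weights,
    edge_count = sum(weights[upper.tri(weights)] != 0),
    settings = settings,
    warnings = warnings,
    betas = betas
  ), class = "ggm_network")
}

#' Estimate a regularized partial-correlation network
#'
#' The full estimator: listwise-deletes incomplete rows, standardizes the
#' columns, runs [nodewise_lasso()] for every node (per-node fold seeds
#' derived from the master seed), applies [threshold_coefficients()], and
#' combines the results with the AND rule via [symmetrize()].
#'
#' The per-node threshold constant `c` in `tau = c * sqrt(log(p)/n)` is,
#' by default (`threshold_c = "l2norm"`), the L2 norm of the node's
#' CV-selected coefficient vector -- the convention of the
#' nodewise-estimation software family this pipeline follows;
#' `threshold_c = "penalty"` instead uses the node's CV-selected penalty
#' weight, a weaker threshold that retains more small edges.
#'
#' @param matrix numeric matrix (participants x variables), `p >= 3`.
#' @param folds CV folds (default 10).
#' @param seed master seed; identical matrix and seed give a bit-identical
#'   network.
#' @param threshold logical; apply the Loh-Wainwright threshold (default
#'   TRUE).
#' @param threshold_c `"l2norm"` (default) or `"penalty"`; see Details.
#' @param penalty_multiplier passed to [nodewise_lasso()] (default 1).
#' @return A `ggm_network`; `$settings` records folds, rules, seed, and the
#'   per-node selected penalties; `$betas` keeps the thresholded nodewise
#'   coefficients for [predictability()].
#' @export
estimate_network <- function(matrix, folds = 10, seed = 1L,
                             threshold = TRUE,
                             threshold_c = c("l2norm", "penalty"),
                             penalty_multiplier = 1) {
  threshold_c <- match.arg(threshold_c)
  x <- as.matrix(matrix)
  p <- ncol(x)
  if (p < 3) stopf("need at least 3 variables, got %d", p)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x)
  if (n <= folds) stopf("need n > folds after listwise deletion")
  labels <- colnames(x) %||% paste0("V", seq_len(p))
  x <- scale(x)
  if (anyNA(x)) stopf("constant column after standardization")

  betas <- matrix(0, p, p, dimnames = list(labels, labels))
  lambdas <- numeric(p)
  for (i in seq_len(p)) {
    # fold seed travels with the node label, so relabeling-permutation of
    # the columns permutes the estimated network identically
    fit <- nodewise_lasso(x, i, folds = folds,
                          seed = derive_seed(seed, 101,
                                             label_hash(labels[i])),
                          penalty_multiplier = penalty_multiplier)
    b <- fit$coef
    if (threshold) {
      cc <- if (threshold_c == "l2norm") sqrt(sum(b^2)) else fit$lambda
      b <- threshold_coefficients(b, n, p, c = cc)
    }
    betas[i, -i] <- b[labels[-i]]
    lambdas[i] <- fit$lambda
  }
  settings <- list(folds = folds,
                   threshold_rule = if (threshold)
                     sprintf("loh-wainwright: tau = c * sqrt(log(p)/n), c = %s",
                             threshold_c)
                   else "none",
                   symmetrization = "AND-geometric-mean",
                   seed = seed, n = n, lambdas = lambdas)
  net <- symmetrize(betas, labels, settings)
  net$betas <- betas
  net
}

#' Node predictability
#'
#' Per node, the proportion of its variance explained by its neighbors in
#' the estimated network: `R^2 = 1 - RSS/TSS` of the node's thresholded
#' nodewise model, restricted to predictors that survived symmetrization
#' (so a node with no incident edges has exactly `R^2 = 0`), evaluated on
#' the standardized data and clipped below at zero.
#'
#' @param matrix the same data the network was estimated on.
#' @param network a `ggm_network` from [estimate_network()].
#' @return Named numeric vector of per-node R-squared values in `[0, 1)`.
#' @export
predictability <- function(matrix, network) {
  x <- as.matrix(matrix)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  x <- scale(x)
  p <- length(network$labels)
  stopifnot(ncol(x) == p)
  r2 <- stats::setNames(numeric(p), network$labels)
  for (i in seq_len(p)) {
    b <- network$betas[i, ]
    b[network$weights[i, ] == 0] <- 0 # only edge-consistent predictors
    y <- x[, i]
    tss <- sum(y^2)
    if (tss == 0) stopf("zero total variance for node %s", network$labels[i])
    if (all(b == 0)) next
    rss <- sum((y - x %*% b)^2)
    r2[i] <- max(0, 1 - rss / tss)
  }
  r2
}

#' @export
print.ggm_network <- function(x, ...) {
  p <- length(x$labels)
  cat(sprintf("GGM network: %d nodes, %d of %d possible edges\n",
              p, x$edge_count, p * (p - 1) / 2))
  if (x$edge_count > 0) {
    idx <- upper_pairs(p)
    w <- x$weights[idx]
    keep <- order(-abs(w))[seq_len(min(5, sum(w != 0)))]
    keep <- keep[w[keep] != 0]
    for (k in keep) {
      cat(sprintf("  %s--%s: %.3f\n", x$labels[idx[k, 1]],
                  x$labels[idx[k, 2]], w[k]))
    }
    if (x$edge_count > length(keep)) cat("  ...\n")
  }
  if (length(x$warnings)) {
    cat(sprintf("  %d warning(s) recorded\n", length(x$warnings)))
  }
  invisible(x)
}

#' Write / read an estimated network
#'
#' JSON carries labels, settings and the upper-triangle edge list; the TSV
#' edge list has columns `node_a`, `node_b`, `weight` (nonzero edges only).
#' Reading either format restores the weight matrix losslessly (JSON also
#' restores settings).
#'
#' @param network a `ggm_network`.
#' @param path file path (`.json` or `.tsv` chosen by extension).
#' @return `write_network` returns `path` invisibly; `read_network` returns
#'   a `ggm_network`.
#' @export
write_network <- function(network, path) {
  idx <- upper_pairs(length(network$labels))
  w <- network$weights[idx]
  keep <- w != 0
  edges <- data.frame(node_a = network$labels[idx[keep, 1]],
                      node_b = network$labels[idx[keep, 2]],
                      weight = w[keep])
  if (grepl("\\.tsv$", path)) {
    utils::write.table(edges, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  } else {
    settings <- network$settings
    settings$lambdas <- as.list(settings$lambdas %||% numeric())
    jsonlite::write_json(list(labels = network$labels, settings = settings,
                              edges = edges),
                         path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_network
#' @param labels node labels; required when reading a TSV edge list (which
#'   does not record isolated nodes).
#' @export
read_network <- function(path, labels = NULL) {
  if (grepl("\\.tsv$", path)) {
    edges <- utils::read.table(path, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
    labels <- labels %||% sort(unique(c(edges$node_a, edges$node_b)))
    settings <- list()
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    edges <- as.data.frame(obj$edges)
    labels <- obj$labels
    settings <- obj$settings
    settings$lambdas <- unlist(settings$lambdas)
  }
  p <- length(labels)
  w <- matrix(0, p, p, dimnames = list(labels, labels))
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      i <- match(edges$node_a[k], labels); j <- match(edges$node_b[k], labels)
      w[i, j] <- w[j, i] <- edges$weight[k]
    }
  }
  new_ggm_network(labels, w, settings)
}
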