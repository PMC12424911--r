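# Bias-adjusted sample skewness (third standardized moment, G1), the
# convention used throughout: G1 = g1 * sqrt(n(n-1)) / (n-2).
marginal_skewness_vec <- function(x) {
  x <- x[!is.na(x)]
  e1071::skewness(x, type = 2)
}

#' Marginal skewness per variable
#'
#' Bias-adjusted sample skewness (third standardized moment) per column,
#' plus a flag for substantial violation of normality, defined as
#' `|skewness| > 0.5`.
#'
#' @param matrix numeric matrix or data frame (participants x variables).
#' @param flag_threshold absolute-skewness flag cutoff (strict), default 0.5.
#' @return Data frame with columns `variable`, `skewness`, `flagged`.
#' @export
marginal_skewness <- function(matrix, flag_threshold = 0.5) {
  m <- as.matrix(matrix)
  if (any(colSums(!is.na(m)) < 3)) {
    stopf("each column needs >= 3 non-missing values")
  }
  sk <- apply(m, 2, marginal_skewness_vec)
  data.frame(variable = colnames(m) %||% paste0("V", seq_along(sk)),
             skewness = unname(sk),
             flagged = unname(abs(sk) > flag_threshold),
             row.names = NULL)
}

#' Henze-Zirkler test for multivariate normality
#'
#' Computes the Henze-Zirkler statistic with its standard smoothing
#' parameter `beta = ((2p+1) n / 4)^(1/(p+4)) / sqrt(2)` and the lognormal
#' approximation to its null distribution for the p-value.
#'
#' @param matrix complete numeric matrix, `n > p`.
#' @return List with `statistic` and `p_value`.
#' @export
henze_zirkler <- function(matrix) {
  x <- as.matrix(matrix)
  if (anyNA(x)) stopf("Henze-Zirkler requires complete data")
  n <- nrow(x); p <- ncol(x)
  if (n <= p) stopf("Henze-Zirkler requires n > p")
  s <- stats::cov(x) * (n - 1) / n # ML covariance
  ev <- min(eigen(s, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < .Machine$double.eps * 100) stopf("covariance matrix is singular")
  s_inv <- chol2inv(chol(s))
  xc <- sweep(x, 2, colMeans(x))
  # squared Mahalanobis distances, pairwise and to the mean
  m <- xc %*% s_inv %*% t(xc)
  d_i <- diag(m)
  d_ij <- outer(d_i, d_i, "+") - 2 * m

  b <- ((2 * p + 1) * n / 4)^(1 / (p + 4)) / sqrt(2)
  b2 <- b^2
  hz <- n * (mean(exp(-b2 / 2 * d_ij)) -
               2 * (1 + b2)^(-p / 2) * mean(exp(-b2 / (2 * (1 + b2)) * d_i)) +
               (1 + 2 * b2)^(-p / 2))

  # lognormal approximation to the null distribution
  a <- 1 + 2 * b2
  wb <- (1 + b2) * (1 + 3 * b2)
  mu <- 1 - a^(-p / 2) * (1 + p * b2 / a + p * (p + 2) * b2^2 / (2 * a^2))
  si2 <- 2 * (1 + 4 * b2)^(-p / 2) +
    2 * a^(-p) * (1 + 2 * p * b2^2 / a^2 +
                    3 * p * (p + 2) * b2^4 / (4 * a^4)) -
    4 * wb^(-p / 2) * (1 + 3 * p * b2^2 / (2 * wb) +
                         p * (p + 2) * b2^4 / (2 * wb^2))
  pmu <- log(sqrt(mu^4 / (si2 + mu^2)))
  psi <- sqrt(log((si2 + mu^2) / mu^2))
  p_value <- stats::plnorm(hz, meanlog = pmu, sdlog = psi,
                           lower.tail = FALSE)
  list(statistic = hz, p_value = p_value)
}
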