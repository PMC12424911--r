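test_that("nodewise regression recovers a known coefficient and nulls", {
  # independence: all coefficients shrink to zero
  x0 <- sample_gaussian(empty_spec(4), 5000, seed = 21)
  fit0 <- nodewise_lasso(scale(x0), 1, seed = 5)
  expect_true(all(fit0$coef == 0))
  # known system: V1 = 0.7 V2 + noise; compare against the OLS oracle
  set.seed(22)
  v2 <- rnorm(5000); v3 <- rnorm(5000)
  v1 <- 0.7 * v2 + rnorm(5000)
  x <- scale(cbind(V1 = v1, V2 = v2, V3 = v3))
  fit <- nodewise_lasso(x, 1, seed = 6)
  ols <- coef(lm(x[, 1] ~ x[, 2] + x[, 3]))[2]
  expect_equal(unname(fit$coef["V2"]), unname(ols), tolerance = 0.05)
})

test_that("nodewise regression validates inputs", {
  x <- matrix(rnorm(30), 10, 3)
  expect_error(nodewise_lasso(x, 1, folds = 20), "folds")
  xna <- x; xna[1, 1] <- NA
  expect_error(nodewise_lasso(xna, 1), "complete")
})

test_that("thresholding zeroes strictly-below-tau coefficients only", {
  # tau = 0.1 * sqrt(log(15)/250) = 0.010409...
  tau <- 0.1 * sqrt(log(15) / 250)
  expect_equal(tau, 0.0104, tolerance = 1e-3)
  b <- c(0.005, tau, 0.02, -0.005, -0.5)
  out <- threshold_coefficients(b, n = 250, p = 15, c = 0.1)
  expect_equal(out, c(0, tau, 0.02, 0, -0.5))
  # all coefficients above tau pass unchanged
  b2 <- c(0.5, -0.4)
  expect_equal(threshold_coefficients(b2, 250, 15, c = 0.1), b2)
})

test_that("symmetrization applies the AND rule with geometric-mean weights", {
  betas <- matrix(0, 3, 3)
  betas[1, 2] <- 0.3 # one-directional: no edge
  net <- symmetrize(betas)
  expect_equal(net$weights[1, 2], 0)
  expect_equal(net$edge_count, 0)

  betas[2, 1] <- 0.3; betas[1, 2] <- 0.3
  net2 <- symmetrize(betas)
  expect_equal(net2$weights[1, 2], 0.3)

  betas[1, 2] <- 0.2; betas[2, 1] <- 0.45
  net3 <- symmetrize(betas)
  expect_equal(net3$weights[1, 2], 0.3, tolerance = 1e-12) # sqrt(0.09)

  betas[1, 2] <- -0.2 # conflicting signs: dropped with a recorded warning
  net4 <- symmetrize(betas)
  expect_equal(net4$weights[1, 2], 0)
  expect_length(net4$warnings, 1)
  expect_match(net4$warnings, "conflicting")
})

test_that("estimated weights match brute-force partial correlations at large n", {
  spec <- generate_true_network(4, 0.5, seed = 31)
  x <- sample_gaussian(spec, 50000, seed = 32)
  net <- estimate_network(x, seed = 33)
  oracle <- partial_cor_oracle(cov(x))
  est <- net$weights
  expect_lt(max(abs(est[est != 0] - oracle[est != 0])), 0.03)
  # all true edges recovered with accurate weights
  expect_true(all(est[spec$adjacency] != 0))
  expect_lt(max(abs(est - spec$partial_corr)), 0.03)
})

test_that("independence data yields an essentially empty network", {
  # CV-selected penalties occasionally admit a near-zero spurious edge
  # even at large n; the estimated network must be empty up to such
  # negligible edges
  x <- sample_gaussian(empty_spec(6), 5000, seed = 41)
  net <- estimate_network(x, seed = 42)
  expect_lte(net$edge_count, 2)
  if (net$edge_count > 0) {
    expect_lt(max(abs(net$weights)), 0.05)
  }
})

test_that("estimation is deterministic and permutation-equivariant", {
  spec <- generate_true_network(5, 0.4, seed = 2)
  x <- sample_gaussian(spec, 400, seed = 3)
  n1 <- estimate_network(x, seed = 9)
  n2 <- estimate_network(x, seed = 9)
  expect_identical(n1, n2)
  perm <- c(3, 1, 5, 2, 4)
  n3 <- estimate_network(x[, perm], seed = 9)
  expect_equal(n1$weights[perm, perm], n3$weights, tolerance = 1e-6)
})

test_that("a tenfold penalty never adds edges", {
  spec <- generate_true_network(6, 0.4, seed = 51)
  x <- sample_gaussian(spec, 300, seed = 52)
  base <- estimate_network(x, seed = 53)
  sparser <- estimate_network(x, seed = 53, penalty_multiplier = 10)
  expect_lte(sparser$edge_count, base$edge_count)
  # and the infinite-penalty limit is empty
  empty <- estimate_network(x, seed = 53, penalty_multiplier = 1e6)
  expect_equal(empty$edge_count, 0)
})

test_that("network invariants hold on estimated networks", {
  spec <- generate_true_network(6, 0.3, seed = 61)
  x <- sample_gaussian(spec, 500, seed = 62)
  net <- estimate_network(x, seed = 63)
  expect_equal(net$weights, t(net$weights), tolerance = 1e-12)
  expect_true(all(diag(net$weights) == 0))
  expect_true(all(abs(net$weights) < 1))
  expect_equal(net$edge_count,
               sum(net$weights[upper.tri(net$weights)] != 0))
})

test_that("predictability reflects explained variance and isolates nodes", {
  set.seed(71)
  v2 <- rnorm(8000); v3 <- rnorm(8000); v4 <- rnorm(8000)
  v1 <- 0.7 * v2 + rnorm(8000)
  x <- cbind(V1 = v1, V2 = v2, V3 = v3, V4 = v4)
  net <- estimate_network(x, seed = 72)
  r2 <- predictability(x, net)
  # variance decomposition: R^2 = 0.49/1.49
  expect_equal(unname(r2["V1"]), 0.49 / 1.49, tolerance = 0.03)
  expect_equal(unname(r2["V3"]), 0)
  expect_equal(unname(r2["V4"]), 0)
  expect_true(all(r2 >= 0 & r2 < 1))
})

test_that("networks round-trip through JSON and TSV", {
  spec <- generate_true_network(5, 0.5, seed = 81)
  x <- sample_gaussian(spec, 800, seed = 82)
  net <- estimate_network(x, seed = 83)
  jpath <- withr::local_tempfile(fileext = ".json")
  tpath <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, jpath)
  write_network(net, tpath)
  bj <- read_network(jpath)
  bt <- read_network(tpath, labels = net$labels)
  expect_equal(bj$weights, net$weights, tolerance = 1e-12)
  expect_equal(bt$weights, net$weights, tolerance = 1e-12)
  expect_equal(bj$settings$folds, net$settings$folds)
  expect_equal(bj$edge_count, net$edge_count)
})
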