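test_that("recovery metrics agree with exhaustive hand enumeration", {
  # 4-node truth with edges (1,2) = 0.3 and (3,4) = -0.2
  pc_t <- matrix(0, 4, 4)
  pc_t[1, 2] <- pc_t[2, 1] <- 0.3
  pc_t[3, 4] <- pc_t[4, 3] <- -0.2
  truth <- true_network_from_partial(pc_t)
  # estimate: (1,2) = 0.25, (3,4) missed, spurious (1,3) = 0.1
  w_e <- matrix(0, 4, 4, dimnames = list(truth$labels, truth$labels))
  w_e[1, 2] <- w_e[2, 1] <- 0.25
  w_e[1, 3] <- w_e[3, 1] <- 0.1
  est <- symmetrize(w_e, labels = truth$labels)
  est$weights <- w_e
  est$edge_count <- 2
  m <- recovery_metrics(truth, est)
  # hand enumeration over the six pairs (1,2),(1,3),(2,3),(1,4),(2,4),(3,4):
  # |0.25-0.3| + |0.1-0| + 0 + 0 + 0 + |0-(-0.2)| = 0.35 over 6 pairs
  expect_equal(m$error, 0.35 / 6, tolerance = 1e-12)
  expect_equal(m$sensitivity, 0.5) # (1,2) found, (3,4) missed
  expect_equal(m$specificity, 3 / 4) # (1,3) spurious among 4 non-edges
  # correlation oracle computed from the explicit 6-vectors
  wt <- c(0.3, 0, 0, 0, 0, -0.2)
  we <- c(0.25, 0.1, 0, 0, 0, 0)
  expect_equal(m$correlation, cor(wt, we), tolerance = 1e-12)
  expect_true(m$correlation_defined)
})

test_that("recovery metrics honour the stated degenerate conventions", {
  pc_t <- matrix(0, 4, 4)
  pc_t[1, 2] <- pc_t[2, 1] <- 0.3
  truth <- true_network_from_partial(pc_t)
  # identical estimate: perfect scores
  perfect <- symmetrize(pc_t, labels = truth$labels)
  perfect$weights <- truth$partial_corr
  perfect$edge_count <- 1
  m0 <- recovery_metrics(truth, perfect)
  expect_equal(m0$error, 0)
  expect_equal(m0$sensitivity, 1)
  expect_equal(m0$specificity, 1)
  expect_equal(m0$correlation, 1)
  # empty estimate: sensitivity 0, specificity 1, correlation undefined -> 0
  empty <- symmetrize(matrix(0, 4, 4), labels = truth$labels)
  m1 <- recovery_metrics(truth, empty)
  expect_equal(m1$sensitivity, 0)
  expect_equal(m1$specificity, 1)
  expect_equal(m1$correlation, 0)
  expect_false(m1$correlation_defined)
  # label mismatch raises
  other <- symmetrize(matrix(0, 4, 4), labels = paste0("X", 1:4))
  expect_error(recovery_metrics(truth, other), "labels")
})

test_that("simulation runs are reproducible from the seed", {
  cfg <- simulation_config(sample_sizes = 150, variable_counts = 5,
                           densities = "medium", replicates = 2, seed = 7)
  r1 <- run_simulation(cfg, verbose = FALSE)
  r2 <- run_simulation(cfg, verbose = FALSE)
  expect_identical(r1$cells, r2$cells)
})

test_that("recovery improves with sample size at fixed p and density", {
  cfg <- simulation_config(sample_sizes = c(100, 250, 1000),
                           variable_counts = 10, densities = "low",
                           replicates = 10, seed = 21)
  res <- run_simulation(cfg, verbose = FALSE)
  sens <- res$cells$sensitivity_mean[order(res$cells$n)]
  expect_true(all(diff(sens) >= -1e-12))
  err <- res$cells$error_mean[order(res$cells$n)]
  expect_lt(err[3], err[1])
})

test_that("specificity stays high under an edgeless truth", {
  truth <- empty_spec(10)
  specs <- sapply(1:10, function(s) {
    x <- sample_gaussian(truth, 250, seed = 600 + s)
    est <- estimate_network(x, seed = 700 + s)
    recovery_metrics(truth, est)$specificity
  })
  expect_gte(mean(specs), 0.9)
})

test_that("simulation results and configs round-trip through files", {
  cfg <- simulation_config(sample_sizes = 150, variable_counts = 5,
                           densities = "medium", replicates = 2, seed = 7)
  res <- run_simulation(cfg, verbose = FALSE)
  cpath <- withr::local_tempfile(fileext = ".csv")
  jpath <- withr::local_tempfile(fileext = ".json")
  write_simulation_result(res, cpath)
  write_simulation_result(res, jpath)
  tidy <- read.csv(cpath)
  expect_equal(nrow(tidy), 4) # one row per metric for the single cell
  expect_setequal(tidy$metric,
                  c("error", "sensitivity", "specificity", "correlation"))
  # config round trip via YAML
  ypath <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(sample_sizes = 150, variable_counts = 5,
                        densities = "medium", replicates = 2, seed = 7),
                   ypath)
  cfg2 <- read_simulation_config(ypath)
  expect_equal(cfg2$sample_sizes, cfg$sample_sizes)
  expect_equal(cfg2$replicates, cfg$replicates)
})
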