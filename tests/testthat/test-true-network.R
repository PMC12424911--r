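test_that("spec built from an explicit single-edge matrix round-trips through covariance inversion", {
  pc <- matrix(0, 3, 3)
  pc[1, 2] <- pc[2, 1] <- 0.5
  spec <- true_network_from_partial(pc)
  # brute-force oracle: invert the implied covariance and recompute
  sigma <- solve(spec$precision)
  oracle <- partial_cor_oracle(sigma)
  expect_equal(oracle[1, 2], 0.5, tolerance = 1e-10)
  expect_equal(oracle[1, 3], 0, tolerance = 1e-10)
  expect_equal(oracle[2, 3], 0, tolerance = 1e-10)
  expect_equal(spec$repair$delta, 0)
})

test_that("empty partial-correlation matrix gives a diagonal precision", {
  spec <- empty_spec(5)
  expect_equal(unname(spec$precision), diag(5))
  expect_true(all(spec$partial_corr == 0))
  expect_equal(sum(spec$adjacency), 0)
})

test_that("generated networks are positive definite with density in the target band", {
  spec <- generate_true_network(15, density = 0.2, seed = 7)
  ev <- eigen(spec$precision, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_lte(abs(spec$realized_density - 0.2), 0.05)
  expect_gte(sum(spec$adjacency[upper.tri(spec$adjacency)]), 1)
  # self-consistency: stored partial correlations equal those implied by
  # the stored precision via full covariance inversion
  oracle <- partial_cor_oracle(solve(spec$precision))
  expect_equal(max(abs(oracle - spec$partial_corr)), 0, tolerance = 1e-10)
})

test_that("generator rejects invalid densities and sizes", {
  expect_error(generate_true_network(15, density = 0), "density")
  expect_error(generate_true_network(15, density = 1), "density")
  expect_error(generate_true_network(2, density = 0.2), "p must be")
})

test_that("denser networks carry systematically weaker partial correlations", {
  mean_w <- sapply(c(0.1, 0.5), function(d) {
    mean(sapply(1:20, function(s) {
      spec <- generate_true_network(15, d, seed = s)
      mean(abs(spec$partial_corr[spec$adjacency]))
    }))
  })
  expect_gt(mean_w[1], 2 * mean_w[2])
})

test_that("mean realized density is calibrated over many seeds", {
  for (target in c(0.1, 0.3, 0.5)) {
    realized <- sapply(1:50, function(s) {
      generate_true_network(15, target, seed = s)$realized_density
    })
    expect_lte(abs(mean(realized) - target), 0.02)
  }
})

test_that("published 15-variable spec carries the printed edge weights", {
  spec <- chronic_pain_network_spec()
  pc <- spec$partial_corr
  expect_equal(pc["mood_symptoms", "stress"], 0.46, tolerance = 0.02)
  expect_equal(pc["pain_worry", "pain_acceptance"], -0.30, tolerance = 0.02)
  expect_equal(pc["pain_intensity", "pain_disability"], 0.35,
               tolerance = 0.02)
  expect_equal(pc["quality_of_life", "positive_affect"], 0.30,
               tolerance = 0.02)
  # an unlisted pair is absent by construction
  expect_identical(pc["discrimination", "pain_intensity"], 0)
  expect_equal(sum(spec$adjacency[upper.tri(spec$adjacency)]), 11)
  expect_lte(spec$repair$max_weight_deviation, 0.02)
})

test_that("gaussian sampler matches its spec's dependence structure", {
  # independence case
  x <- sample_gaussian(empty_spec(5), 10000, seed = 4)
  off <- cor(x)[upper.tri(diag(5))]
  expect_lt(max(abs(off)), 0.05)
  # shape contract at minimal n
  x2 <- sample_gaussian(chronic_pain_network_spec(), 2, seed = 1)
  expect_equal(dim(x2), c(2, 15))
  # consistency: sample partial correlations converge to the spec's
  spec <- chronic_pain_network_spec()
  xl <- sample_gaussian(spec, 100000, seed = 8)
  pc_hat <- partial_cor_oracle(cov(xl))
  expect_lt(max(abs(pc_hat - spec$partial_corr)), 0.02)
})

test_that("sampler is deterministic in the seed and validates n", {
  spec <- generate_true_network(6, 0.3, seed = 1)
  expect_identical(sample_gaussian(spec, 50, seed = 2),
                   sample_gaussian(spec, 50, seed = 2))
  expect_error(sample_gaussian(spec, 1, seed = 2), "n must be")
})

test_that("network spec JSON round trip preserves the matrices", {
  spec <- generate_true_network(10, 0.3, seed = 12)
  path <- withr::local_tempfile(fileext = ".json")
  write_network_spec(spec, path)
  back <- read_network_spec(path)
  expect_equal(back$labels, spec$labels)
  expect_equal(back$partial_corr, spec$partial_corr, tolerance = 1e-12)
  expect_equal(back$precision, spec$precision, tolerance = 1e-12)
})
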