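test_that("CPGS mean-times-10 and composite-sum rules reproduce hand-computed scores", {
  map <- default_scoring_map()
  tab <- emulate_survey(survey_config(n_participants = 10, missing_rate = 0,
                                      seed = 1))
  tab[1, paste0("cpgs_", 1:3)] <- c(5, 6, 7)
  tab[1, paste0("cpgs_", 5:7)] <- c(2, 4, 6)
  tab[1, paste0("phq_", 1:2)] <- c(2, 3)
  tab[1, paste0("gad_", 1:2)] <- c(1, 1)
  sc <- score_variables(tab, map)
  expect_equal(unname(sc[1, "pain_intensity"]), 60)
  expect_equal(unname(sc[1, "pain_disability"]), 40)
  expect_equal(unname(sc[1, "mood_symptoms"]), 7)
  expect_equal(unname(sc[1, "depressive_symptoms"]), 5)
  expect_equal(unname(sc[1, "anxious_symptoms"]), 2)
})

test_that("reverse coding reflects on the item scale and is an involution", {
  tab <- rbind(good_row("P1", b2 = 1))
  sc <- score_variables(tab, tiny_map())
  # b: b1 = 2 plus reflected b2 = 1+5-1 = 5 -> 7
  expect_equal(unname(sc[1, "b"]), 7)
  # reflecting twice returns the original response
  reflect <- function(x, lo, hi) lo + hi - x
  for (x in 0:4) expect_equal(reflect(reflect(x, 0, 4), 0, 4), x)
  # response 1 on a 0-4 reverse-coded item recodes to 3
  expect_equal(reflect(1, 0, 4), 3)
})

test_that("person-mean imputation scores participants with half the items missing", {
  tab <- rbind(good_row("P1"), good_row("P2", a1 = NA))
  sc <- score_variables(tab, tiny_map())
  # a2 = 2, a3 = 3 -> person mean 2.5 over 3 items -> 7.5
  expect_equal(unname(sc["P2", "a"]), 7.5)
  # more than half missing scores NA
  tab3 <- rbind(good_row("P1"), good_row("P3", a1 = NA, a2 = NA))
  sc3 <- score_variables(tab3, tiny_map())
  expect_true(is.na(sc3["P3", "a"]))
})

test_that("sum-rule scoring is linear in the items", {
  tab <- rbind(good_row("P1", a1 = 1, a2 = 1, a3 = 2))
  map <- scoring_map(list(list(name = "a", items = c("a1", "a2", "a3"),
                               reverse_coded = character(),
                               scale = c(0, 100), rule = "sum")))
  s1 <- score_variables(tab, map)[1, "a"]
  tab2 <- tab
  tab2[, c("a1", "a2", "a3")] <- tab[, c("a1", "a2", "a3")] * 3
  s2 <- score_variables(tab2, map)[1, "a"]
  expect_equal(unname(s2), unname(s1) * 3)
})

test_that("out-of-range responses are rejected", {
  tab <- rbind(good_row("P1", a1 = 9))
  expect_error(score_variables(tab, tiny_map()), "out of range")
})

test_that("Cronbach's alpha matches a covariance-based hand computation", {
  set.seed(20)
  lat <- rnorm(40)
  block <- cbind(i1 = lat + rnorm(40, sd = 0.6),
                 i2 = lat + rnorm(40, sd = 0.6),
                 i3 = lat + rnorm(40, sd = 0.6))
  # oracle via the covariance-matrix identity: var(total) = sum of all
  # entries of the item covariance matrix
  cv <- cov(block)
  alpha_oracle <- 3 / 2 * (1 - sum(diag(cv)) / sum(cv))
  expect_equal(cronbach_alpha(block), alpha_oracle, tolerance = 1e-12)
})

test_that("Cronbach's alpha handles the degenerate consistency cases", {
  x <- rnorm(30)
  expect_equal(cronbach_alpha(cbind(x, x)), 1, tolerance = 1e-12)
  # exactly orthogonal columns: alpha = 0
  a <- c(1, -1, 1, -1); b <- c(1, 1, -1, -1)
  expect_equal(cronbach_alpha(cbind(a, b)), 0, tolerance = 1e-12)
  expect_error(cronbach_alpha(cbind(a)), ">= 2 items")
  expect_error(cronbach_alpha(cbind(c(1, 1, 1), c(2, 2, 2))), "variance")
})

test_that("reliability of the emulated battery is in the intended range", {
  tab <- emulate_survey(survey_config(n_participants = 500,
                                      missing_rate = 0, seed = 11))
  rel <- reliability_table(tab, default_scoring_map())
  multi <- rel$alpha[rel$n_items >= 3]
  expect_true(all(multi > 0.6))
})

test_that("variable matrices round-trip through CSV with provenance", {
  tab <- emulate_survey(survey_config(n_participants = 25, seed = 2))
  sc <- score_variables(tab, default_scoring_map())
  path <- withr::local_tempfile(fileext = ".csv")
  write_variable_matrix(sc, path)
  back <- read_variable_matrix(path)
  expect_equal(attr(back, "provenance"), "raw")
  expect_equal(unclass(back), unclass(sc), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(rownames(back), rownames(sc))
})
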