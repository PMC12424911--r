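# Small in-code fixtures shared across test files.

# Minimal three-variable scoring map: a sum scale, a sum scale with one
# reverse-coded item, and a CPGS-style mean-times-10 scale.
tiny_map <- function() {
  scoring_map(list(
    list(name = "a", items = c("a1", "a2", "a3"), reverse_coded = character(),
         scale = c(0, 4), rule = "sum"),
    list(name = "b", items = c("b1", "b2"), reverse_coded = "b2",
         scale = c(1, 5), rule = "sum"),
    list(name = "c", items = c("c1", "c2", "c3"), reverse_coded = character(),
         scale = c(0, 10), rule = "mean_times_10")
  ))
}

# One well-formed participant row for tiny_map(); fields overridable.
good_row <- function(id, ...) {
  row <- list(participant_id = id, duration_minutes = 20,
              attention_checks_failed = 0, consent = TRUE,
              pain_past_6mo = TRUE, pain_duration_months = 24,
              language = "en",
              a1 = 1, a2 = 2, a3 = 3, b1 = 2, b2 = 4,
              c1 = 5, c2 = 6, c3 = 7)
  over <- list(...)
  row[names(over)] <- over
  as.data.frame(row, stringsAsFactors = FALSE)
}

# 50-row cleaning fixture with known memberships per exclusion rule, in the
# order the filters are applied: 2 without consent, 3 without recent pain,
# 2 with pain under 3 months, 2 rows sharing one id (1 duplicate removal),
# 3 with no item responses, 2 speeders, 1 with >= 2 failed attention
# checks, 3 missing > 50% of the items of variable "a"; 33 rows survive.
cleaning_fixture <- function() {
  rows <- list()
  add <- function(r) rows[[length(rows) + 1]] <<- r
  for (i in 1:2) add(good_row(sprintf("NC%02d", i), consent = FALSE))
  for (i in 1:3) add(good_row(sprintf("NP%02d", i), pain_past_6mo = FALSE))
  for (i in 1:2) add(good_row(sprintf("SD%02d", i), pain_duration_months = 2))
  for (i in 1:2) add(good_row("DUP01")) # second occurrence is the duplicate
  for (i in 1:3) {
    add(good_row(sprintf("EM%02d", i), a1 = NA, a2 = NA, a3 = NA, b1 = NA,
                 b2 = NA, c1 = NA, c2 = NA, c3 = NA))
  }
  for (i in 1:2) add(good_row(sprintf("SP%02d", i), duration_minutes = 3))
  add(good_row("AT01", attention_checks_failed = 2))
  for (i in 1:3) add(good_row(sprintf("MI%02d", i), a1 = NA, a2 = NA))
  for (i in seq_len(50 - length(rows) - 1)) add(good_row(sprintf("OK%02d", i)))
  add(good_row("AT00", attention_checks_failed = 1)) # 1 failure: retained
  do.call(rbind, rows)
}

# Four-node chain spec with constant edge weight.
chain_spec <- function(w = 0.3, p = 4) {
  pc <- matrix(0, p, p)
  for (i in seq_len(p - 1)) pc[i, i + 1] <- pc[i + 1, i] <- w
  true_network_from_partial(pc)
}

# Empty (independence) spec: identity precision.
empty_spec <- function(p = 5) {
  true_network_from_partial(matrix(0, p, p))
}

# Brute-force partial correlations from a covariance matrix by full
# inversion: pc_ij = -K_ij / sqrt(K_ii K_jj), K = solve(sigma).
partial_cor_oracle <- function(sigma) {
  k <- solve(sigma)
  p <- nrow(k)
  pc <- matrix(0, p, p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i != j) pc[i, j] <- -k[i, j] / sqrt(k[i, i] * k[j, j])
    }
  }
  pc
}
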