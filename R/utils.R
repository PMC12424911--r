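# Deterministic sub-seed derivation: every stage that consumes randomness
# gets its own 32-bit seed from the master seed plus a stream index, so
# replicates/nodes can be recomputed independently and in any order.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  m <- 2147483647 # 2^31 - 1
  s <- as.double(seed %% m)
  for (k in idx) {
    s <- (s * 48271 + as.double(k) * 7919 + 1) %% m
  }
  as.integer(s)
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Upper-triangle index pairs (i < j) in column-major order, as a 2-column
# matrix; the canonical edge ordering used by every writer and summary.
upper_pairs <- function(p) {
  which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
}

upper_vec <- function(m) m[upper.tri(m)]

edge_names <- function(labels) {
  idx <- upper_pairs(length(labels))
  paste(labels[idx[, 1]], labels[idx[, 2]], sep = "--")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic polynomial hash of a label, used to give each node a fold
# seed that travels with the node under column permutation.
label_hash <- function(s) {
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 268435399
  as.integer(h)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
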