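#' Score questionnaire items into variables
#'
#' Reverse-codes flagged items (`x -> min + max - x` on the item's scale),
#' then aggregates per the variable's rule: `"sum"` and `"composite_sum"`
#' sum the items; `"mean_times_10"` takes the item mean times 10 (the
#' Chronic Pain Grade Scale convention, giving 0-100 scores). A participant
#' missing at most half of a variable's items is scored by person-mean
#' imputation across that variable's available items; with more than half
#' missing the score is `NA` (such rows are normally removed upstream by
#' [clean_sample()]).
#'
#' @param table cleaned participant table.
#' @param map a `scoring_map`.
#' @return A `variable_matrix`: numeric matrix (participants x variables)
#'   with `participant_id` rownames and a `provenance` attribute `"raw"`.
#' @export
score_variables <- function(table, map) {
  scores <- matrix(NA_real_, nrow(table), length(map),
                   dimnames = list(table$participant_id, names(map)))
  for (v in map) {
    vi <- v$items
    missing_items <- setdiff(vi, names(table))
    if (length(missing_items)) {
      stopf("items of '%s' absent from table: %s", v$name,
            paste(missing_items, collapse = ", "))
    }
    block <- as.matrix(table[, vi, drop = FALSE])
    rng <- range(block, na.rm = TRUE)
    if (rng[1] < v$scale[1] || rng[2] > v$scale[2]) {
      stopf("responses out of range [%g, %g] for variable '%s'",
            v$scale[1], v$scale[2], v$name)
    }
    rc <- v$reverse_coded %||% character()
    if (length(rc)) {
      block[, rc] <- v$scale[1] + v$scale[2] - block[, rc]
    }
    frac_missing <- rowMeans(is.na(block))
    pmean <- rowMeans(block, na.rm = TRUE)
    k <- length(vi)
    score <- switch(v$rule,
      sum = ,
      composite_sum = pmean * k, # person-mean imputation then sum
      mean_times_10 = pmean * 10
    )
    score[frac_missing > 0.5] <- NA_real_
    score[is.nan(score)] <- NA_real_
    scores[, v$name] <- score
  }
  attr(scores, "provenance") <- "raw"
  class(scores) <- c("variable_matrix", class(scores))
  scores
}

#' Cronbach's alpha for a participant-by-item block
#'
#' `alpha = k/(k-1) * (1 - sum of item variances / variance of the total)`,
#' computed on complete rows only.
#'
#' @param items numeric matrix or data frame, one column per item.
#' @return Scalar alpha.
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  if (ncol(items) < 2) stopf("Cronbach's alpha needs >= 2 items")
  items <- items[stats::complete.cases(items), , drop = FALSE]
  if (nrow(items) < 3) stopf("Cronbach's alpha needs >= 3 complete rows")
  k <- ncol(items)
  total_var <- stats::var(rowSums(items))
  if (total_var == 0) stopf("total-score variance is zero")
  k / (k - 1) * (1 - sum(apply(items, 2, stats::var)) / total_var)
}

#' Internal-consistency table for all multi-item variables
#'
#' @param table cleaned participant table (items on their original scale;
#'   reverse-coded items are reflected before computing alpha).
#' @param map a `scoring_map`.
#' @return Data frame with columns `variable`, `n_items`, `alpha` (NA for
#'   single-item variables).
#' @export
reliability_table <- function(table, map) {
  rows <- lapply(map, function(v) {
    a <- NA_real_
    if (length(v$items) >= 2) {
      block <- as.matrix(table[, v$items, drop = FALSE])
      rc <- v$reverse_coded %||% character()
      if (length(rc)) block[, rc] <- v$scale[1] + v$scale[2] - block[, rc]
      a <- tryCatch(cronbach_alpha(block), error = function(e) NA_real_)
    }
    data.frame(variable = v$name, n_items = length(v$items), alpha = a)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read a variable matrix as CSV
#'
#' First column `participant_id`, then one numeric column per variable; the
#' `provenance` flag (`"raw"` or `"transformed"`) is stored in a comment
#' header line.
#'
#' @param matrix a `variable_matrix`.
#' @param path file path.
#' @return `write_variable_matrix` returns `path` invisibly;
#'   `read_variable_matrix` returns a `variable_matrix`.
#' @export
write_variable_matrix <- function(matrix, path) {
  prov <- attr(matrix, "provenance") %||% "raw"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# provenance: %s", prov), con)
  df <- data.frame(participant_id = rownames(matrix),
                   as.data.frame(unclass(matrix)), check.names = FALSE)
  utils::write.csv(df, con, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_variable_matrix
#' @export
read_variable_matrix <- function(path) {
  first <- readLines(path, n = 1)
  prov <- if (grepl("^# provenance:", first)) {
    sub("^# provenance:\\s*", "", first)
  } else "raw"
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        na.strings = c("", "NA"), check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$participant_id
  attr(m, "provenance") <- prov
  class(m) <- c("variable_matrix", class(m))
  m
}
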