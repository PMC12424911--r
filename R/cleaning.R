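#' Participant-level cleaning thresholds
#'
#' Defaults follow the emulated study: eligibility requires pain in the past
#' six months and a pain duration of at least 3 months; speeders are
#' participants finishing in under 5 minutes; attention failures means two
#' or more of five checks wrong; the missingness rule drops participants
#' missing more than 50% of the items of at least one scored variable.
#'
#' @param min_duration_minutes speed filter cutoff (exclusive).
#' @param max_attention_failures exclusion at this many failures or more.
#' @param max_missing_fraction per-variable item-missingness bound
#'   (exclusive: strictly more than this fraction excludes).
#' @param min_pain_duration_months eligibility bound (inclusive).
#' @return A named list of thresholds.
#' @export
cleaning_thresholds <- function(min_duration_minutes = 5,
                                max_attention_failures = 2,
                                max_missing_fraction = 0.5,
                                min_pain_duration_months = 3) {
  list(min_duration_minutes = min_duration_minutes,
       max_attention_failures = max_attention_failures,
       max_missing_fraction = max_missing_fraction,
       min_pain_duration_months = min_pain_duration_months)
}

#' Clean a participant table with the study's exclusion rules
#'
#' Applies, in this order: (1) no consent / ineligible, (2) no pain in the
#' past six months, (3) pain duration under the minimum, (4) duplicate
#' participant ids, (5) no responses beyond demographics and pain
#' characteristics (all item cells empty), (6) speeders, (7) two or more
#' attention-check failures, (8) more than 50% of the items missing for at
#' least one scored variable. Counts are order-dependent: each rule only
#' sees participants that survived the previous rules, and the report
#' records the order explicitly.
#'
#' @param table data frame with the metadata columns of
#'   [emulate_survey()] plus item columns.
#' @param map a `scoring_map`; defines which item columns exist and which
#'   variable each belongs to for the missingness rule.
#' @param thresholds see [cleaning_thresholds()].
#' @return A list with `table` (survivors) and `report` (a
#'   `cleaning_report`: per-rule removal counts in application order, `n_in`,
#'   `n_out`).
#' @export
clean_sample <- function(table, map, thresholds = cleaning_thresholds()) {
  if (nrow(table) == 0) stopf("participant table is empty")
  required <- c("participant_id", "duration_minutes",
                "attention_checks_failed", "consent", "pain_past_6mo",
                "pain_duration_months")
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols)) {
    stopf("missing metadata columns: %s", paste(missing_cols, collapse = ", "))
  }
  items <- intersect(unique(unlist(lapply(map, `[[`, "items"))), names(table))
  if (!length(items)) stopf("no scoring-map items found in table")

  n_in <- nrow(table)
  counts <- c(no_consent = 0, no_pain = 0, duration_too_short_pain = 0,
              duplicates = 0, empty_beyond_demographics = 0, speeders = 0,
              attention_failures = 0, excess_missing = 0)

  drop_rule <- function(tab, rule, bad) {
    counts[rule] <<- sum(bad)
    tab[!bad, , drop = FALSE]
  }

  tab <- table
  tab <- drop_rule(tab, "no_consent", !tab$consent %in% TRUE)
  tab <- drop_rule(tab, "no_pain", !tab$pain_past_6mo %in% TRUE)
  tab <- drop_rule(tab, "duration_too_short_pain",
                   is.na(tab$pain_duration_months) |
                     tab$pain_duration_months <
                       thresholds$min_pain_duration_months)
  tab <- drop_rule(tab, "duplicates", duplicated(tab$participant_id))
  all_empty <- rowSums(!is.na(tab[, items, drop = FALSE])) == 0
  tab <- drop_rule(tab, "empty_beyond_demographics", all_empty)
  tab <- drop_rule(tab, "speeders",
                   tab$duration_minutes < thresholds$min_duration_minutes)
  tab <- drop_rule(tab, "attention_failures",
                   tab$attention_checks_failed >=
                     thresholds$max_attention_failures)
  # per-variable missingness: > max_missing_fraction of a variable's items
  excess <- rep(FALSE, nrow(tab))
  for (v in map) {
    vi <- intersect(v$items, names(tab))
    if (!length(vi)) next
    frac <- rowMeans(is.na(tab[, vi, drop = FALSE]))
    excess <- excess | frac > thresholds$max_missing_fraction
  }
  tab <- drop_rule(tab, "excess_missing", excess)

  report <- structure(list(counts = counts, order = names(counts),
                           n_in = n_in, n_out = nrow(tab),
                           thresholds = thresholds),
                      class = "cleaning_report")
  stopifnot(report$n_out == n_in - sum(counts))
  list(table = tab, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf("Cleaning report: %d in, %d out\n", x$n_in, x$n_out))
  for (r in x$order) {
    cat(sprintf("  %-26s -%d\n", r, x$counts[[r]]))
  }
  invisible(x)
}

#' Write / read a cleaning report as JSON
#' @param report a `cleaning_report`.
#' @param path file path.
#' @return `write_cleaning_report` returns `path` invisibly;
#'   `read_cleaning_report` returns a `cleaning_report`.
#' @export
write_cleaning_report <- function(report, path) {
  obj <- unclass(report)
  obj$counts <- as.list(obj$counts) # keep rule names in the JSON object
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cleaning_report
#' @export
read_cleaning_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$counts <- unlist(obj$counts)
  structure(obj, class = "cleaning_report")
}
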