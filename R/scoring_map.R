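#' Declarative questionnaire scoring maps
#'
#' A scoring map describes, for each scored variable, which item columns feed
#' it, which of those are reverse-coded, the per-item response-scale bounds,
#' and the aggregation rule. Three rules are supported: `"sum"` (sum of
#' items), `"mean_times_10"` (mean of items times 10, the Chronic Pain Grade
#' Scale convention yielding 0-100 scores), and `"composite_sum"` (sum of
#' items drawn from more than one instrument, e.g. a mood-symptoms composite
#' of the PHQ-2 and GAD-2 totals).
#'
#' @param variables a list; each element is a list with fields `name`,
#'   `items` (character), `reverse_coded` (character subset of `items`),
#'   `scale` (numeric `c(min, max)`), and `rule`.
#' @return A `scoring_map` object (validated).
#' @export
scoring_map <- function(variables) {
  rules <- c("sum", "mean_times_10", "composite_sum")
  for (v in variables) {
    if (is.null(v$name) || is.null(v$items) || is.null(v$scale) ||
        is.null(v$rule)) {
      stopf("each scoring-map variable needs name, items, scale, rule")
    }
    if (!v$rule %in% rules) {
      stopf("unknown rule '%s' for variable '%s'", v$rule, v$name)
    }
    rc <- v$reverse_coded %||% character()
    if (!all(rc %in% v$items)) {
      stopf("reverse_coded items of '%s' are not a subset of its items",
            v$name)
    }
    if (length(v$scale) != 2 || v$scale[1] >= v$scale[2]) {
      stopf("scale of '%s' must be c(min, max) with min < max", v$name)
    }
  }
  names(variables) <- vapply(variables, `[[`, "", "name")
  structure(variables, class = "scoring_map")
}

map_variable <- function(name, items, scale, rule = "sum",
                         reverse_coded = character()) {
  list(name = name, items = items, reverse_coded = reverse_coded,
       scale = scale, rule = rule)
}

#' Built-in scoring map for the chronic-pain survey battery
#'
#' Mirrors the instruments of the study the package emulates: CPGS pain
#' intensity (items 1-3) and disability (items 5-7) scored as mean x 10;
#' PHQ-2 and GAD-2 scored separately and as a combined mood-symptoms
#' composite; sums for the remaining scales. Item contents are synthetic --
#' only the counts, bounds and reverse-coding structure follow the original
#' battery. Reverse-coded items: two of the four perceived-stress items, the
#' discrimination frequency items (asked from "almost every day" to
#' "never"), and the healthcare-access items (agreement scale where low
#' values mean good access).
#'
#' @return A `scoring_map` with 17 variables (the 15 extended-network
#'   variables plus separate anxious/depressive symptom scores used by the
#'   6-variable replication analysis).
#' @export
default_scoring_map <- function() {
  scoring_map(list(
    map_variable("pain_intensity", paste0("cpgs_", 1:3), c(0, 10),
                 "mean_times_10"),
    map_variable("pain_disability", paste0("cpgs_", 5:7), c(0, 10),
                 "mean_times_10"),
    map_variable("quality_of_life", paste0("qol_", 1:8), c(1, 5)),
    map_variable("pain_worry", paste0("cap_", 1:6), c(1, 5)),
    map_variable("pain_beliefs", "sopa_1", c(0, 4)),
    map_variable("pain_avoidance", paste0("aps_", 1:3), c(0, 3)),
    map_variable("pain_acceptance", paste0("cpaq_", 1:2), c(0, 6)),
    map_variable("positive_affect", paste0("panas_", 1:5), c(1, 5)),
    map_variable("depressive_symptoms", paste0("phq_", 1:2), c(0, 3)),
    map_variable("anxious_symptoms", paste0("gad_", 1:2), c(0, 3)),
    map_variable("mood_symptoms", c(paste0("phq_", 1:2), paste0("gad_", 1:2)),
                 c(0, 3), "composite_sum"),
    map_variable("stress", paste0("pss_", 1:4), c(0, 4),
                 reverse_coded = c("pss_2", "pss_3")),
    map_variable("emotional_support", paste0("promis_", 1:4), c(1, 5)),
    map_variable("pain_invalidation", paste0("piv_", 1:12), c(1, 7)),
    map_variable("discrimination", paste0("eds_", 1:2), c(1, 6),
                 reverse_coded = paste0("eds_", 1:2)),
    map_variable("access_healthcare", paste0("psq_", 1:4), c(1, 5),
                 reverse_coded = paste0("psq_", 1:4)),
    map_variable("financial_worry", paste0("fas_", 1:2), c(1, 7))
  ))
}

#' @export
print.scoring_map <- function(x, ...) {
  cat(sprintf("Scoring map: %d variables\n", length(x)))
  for (v in x) {
    cat(sprintf("  %-20s %2d items [%g-%g] %s%s\n", v$name, length(v$items),
                v$scale[1], v$scale[2], v$rule,
                if (length(v$reverse_coded %||% character()))
                  sprintf(" (%d reversed)", length(v$reverse_coded)) else ""))
  }
  invisible(x)
}

#' Read / write a scoring map (YAML or JSON)
#'
#' Format is chosen from the file extension (`.yaml`/`.yml` vs `.json`).
#' Round trips are lossless.
#'
#' @param map a `scoring_map`.
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return `write_scoring_map` returns `path` invisibly; `read_scoring_map`
#'   returns a `scoring_map`.
#' @export
write_scoring_map <- function(map, path) {
  vars <- lapply(unclass(map), function(v) {
    v$reverse_coded <- as.list(v$reverse_coded %||% character())
    v$items <- as.list(v$items)
    v
  })
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(list(variables = unname(vars)), path)
  } else {
    jsonlite::write_json(list(variables = unname(vars)), path,
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_scoring_map
#' @export
read_scoring_map <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  vars <- lapply(obj$variables, function(v) {
    map_variable(v$name, unlist(v$items), unlist(v$scale), v$rule,
                 reverse_coded = as.character(unlist(v$reverse_coded)))
  })
  scoring_map(vars)
}
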