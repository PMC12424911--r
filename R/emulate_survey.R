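#' Configuration for the synthetic survey generator
#'
#' Bundles everything [emulate_survey()] needs: the ground-truth network the
#' latent variable scores are drawn from, the scoring map that defines items
#' per variable, per-variable marginal skew targets, the missing-data rate,
#' and how many careless responders (speeders / attention-check failers) to
#' append.
#'
#' @param n_participants number of genuine participants (>= 10).
#' @param truth a `true_network_spec`; its labels must be variables of `map`.
#' @param map a `scoring_map` describing items per variable; defaults to
#'   [default_scoring_map()].
#' @param skew_targets named numeric of target marginal skewness per
#'   variable, each in `[-1.5, 1.5]`; unnamed variables default to 0. The
#'   default targets give skew +/-0.5 to the five variables the emulated
#'   study flagged as skewed (emotional support negatively; mood symptoms,
#'   pain invalidation, pain-related worry and discrimination positively).
#' @param missing_rate fraction of item cells set missing completely at
#'   random, in `[0, 0.5)`.
#' @param n_careless number of careless-responder rows appended; all of them
#'   finish in under 5 minutes and every second one also fails two or more
#'   attention checks.
#' @param likert logical; discretize items to their Likert scales (default)
#'   or keep them continuous.
#' @param item_loading standardized loading of each item on its variable's
#'   latent score (default 0.8, giving Cronbach's alpha near 0.8-0.9 for
#'   typical item counts).
#' @param seed integer master seed.
#' @return A `survey_config` list.
#' @export
survey_config <- function(n_participants = 262,
                          truth = chronic_pain_network_spec(),
                          map = default_scoring_map(),
                          skew_targets = c(emotional_support = -0.5,
                                           mood_symptoms = 0.5,
                                           pain_invalidation = 0.5,
                                           pain_worry = 0.5,
                                           discrimination = 0.5),
                          missing_rate = 0.02,
                          n_careless = 0,
                          likert = TRUE,
                          item_loading = 0.8,
                          seed = 1L) {
  if (n_participants < 10) stopf("n_participants must be >= 10")
  if (missing_rate < 0 || missing_rate >= 0.5) {
    stopf("missing_rate must be in [0, 0.5)")
  }
  if (!all(truth$labels %in% names(map))) {
    stopf("truth labels missing from scoring map: %s",
          paste(setdiff(truth$labels, names(map)), collapse = ", "))
  }
  sk <- stats::setNames(rep(0, length(truth$labels)), truth$labels)
  if (length(skew_targets)) {
    known <- intersect(names(skew_targets), truth$labels)
    sk[known] <- skew_targets[known]
  }
  if (any(abs(sk) > 1.5)) stopf("skew targets must lie in [-1.5, 1.5]")
  structure(list(n_participants = n_participants, truth = truth, map = map,
                 skew_targets = sk, missing_rate = missing_rate,
                 n_careless = n_careless, likert = likert,
                 item_loading = item_loading, seed = seed),
            class = "survey_config")
}

# Monotone skew-inducing transform g_a(z) = (exp(a z) - 1) / a (identity at
# a = 0); `a` is fitted by root finding so the transformed column hits the
# target sample skewness exactly (a target of 0 removes the sampling skew
# of the finite draw). Monotonicity preserves the copula exactly.
skew_transform <- function(z, target) {
  g <- function(a) if (abs(a) < 1e-8) z else (exp(a * z) - 1) / a
  f <- function(a) marginal_skewness_vec(g(a)) - target
  for (amax in c(4, 8, 16)) {
    if (f(-amax) * f(amax) <= 0) {
      a <- stats::uniroot(f, c(-amax, amax), tol = 1e-8)$root
      return(g(a))
    }
  }
  stopf("skew target %g unreachable", target)
}

# Rescale a continuous column onto a Likert scale and round; cut points are
# anchored at the 0.5% and 99.5% quantiles so outliers saturate the ends.
discretize_likert <- function(x, lo, hi) {
  q <- stats::quantile(x, c(0.005, 0.995), names = FALSE)
  u <- (x - q[1]) / max(q[2] - q[1], .Machine$double.eps)
  pmin(hi, pmax(lo, round(lo + u * (hi - lo))))
}

#' Generate a survey-like participant-by-item table
#'
#' Draws latent variable scores from the configured ground-truth network,
#' builds items from each latent score with independent measurement noise,
#' applies a monotone transform per item so its marginal skewness matches
#' the variable's target (within about +/-0.1 before discretization),
#' discretizes to the item's Likert scale, injects missingness completely at
#' random, and appends careless-responder rows. The returned table carries
#' the metadata columns every cleaning filter needs: `participant_id`,
#' `duration_minutes`, `attention_checks_failed`, `consent`,
#' `pain_past_6mo`, `pain_duration_months` and `language`.
#'
#' Two attributes support property checks on the generator itself:
#' `"latent_items"` (the continuous item matrix before the skew transform)
#' and `"skewed_items"` (after the transform, before discretization).
#'
#' @param config a [survey_config()].
#' @return A data frame with one row per participant (genuine rows first,
#'   then careless rows) and one column per item, plus metadata columns.
#' @export
emulate_survey <- function(config) {
  stopifnot(inherits(config, "survey_config"))
  truth <- config$truth
  map <- config$map
  n <- config$n_participants
  lab <- truth$labels

  z <- sample_gaussian(truth, n, seed = derive_seed(config$seed, 1))

  # Item columns are generated per truth variable; variables in the map that
  # merely re-score a subset of another variable's items (e.g. separate
  # anxious/depressive scores inside a mood composite) reuse those columns.
  item_cols <- list()
  lam <- config$item_loading
  local_seed(derive_seed(config$seed, 2), {
    for (v in lab) {
      spec_v <- map[[v]]
      tgt <- config$skew_targets[[v]]
      for (it in spec_v$items) {
        if (!is.null(item_cols[[it]])) next
        raw <- scale(lam * z[, v] + sqrt(1 - lam^2) * stats::rnorm(n))[, 1]
        x <- skew_transform(raw, tgt)
        pre <- x
        if (config$likert) {
          x <- discretize_likert(x, spec_v$scale[1], spec_v$scale[2])
          if (it %in% (spec_v$reverse_coded %||% character())) {
            # stored responses are on the original (unreflected) scale
            x <- spec_v$scale[1] + spec_v$scale[2] - x
          }
        }
        attr(x, "pre_discretize") <- pre
        attr(x, "pre_skew") <- raw
        item_cols[[it]] <- x
      }
    }
  })

  items <- as.data.frame(lapply(item_cols, as.vector),
                         optional = TRUE, check.names = FALSE)
  skewed <- vapply(item_cols, function(x) attr(x, "pre_discretize"),
                   numeric(n))

  # Missingness, MCAR over item cells.
  if (config$missing_rate > 0) {
    local_seed(derive_seed(config$seed, 3), {
      mask <- matrix(stats::runif(n * ncol(items)) < config$missing_rate,
                     n, ncol(items))
      for (j in seq_len(ncol(items))) items[mask[, j], j] <- NA
    })
  }

  meta <- local_seed(derive_seed(config$seed, 4), data.frame(
    participant_id = sprintf("P%05d", seq_len(n)),
    duration_minutes = pmax(7, stats::rlnorm(n, log(30), 0.4)),
    attention_checks_failed = stats::rbinom(n, 1, 0.05),
    consent = TRUE,
    pain_past_6mo = TRUE,
    pain_duration_months = round(stats::runif(n, 3, 240)),
    language = sample(c("en", "de", "nl"), n, TRUE,
                      prob = c(0.70, 0.21, 0.09)),
    stringsAsFactors = FALSE
  ))
  out <- cbind(meta, items)

  if (config$n_careless > 0) {
    nc <- config$n_careless
    careless <- local_seed(derive_seed(config$seed, 5), {
      resp <- as.data.frame(lapply(names(item_cols), function(it) {
        sc <- item_scale(map, it)
        sample(seq(sc[1], sc[2]), nc, TRUE)
      }), optional = TRUE)
      names(resp) <- names(item_cols)
      cm <- data.frame(
        participant_id = sprintf("C%05d", seq_len(nc)),
        duration_minutes = stats::runif(nc, 1, 4.5),
        attention_checks_failed = ifelse(seq_len(nc) %% 2 == 0,
                                         sample(2:4, nc, TRUE), 0),
        consent = TRUE,
        pain_past_6mo = TRUE,
        pain_duration_months = round(stats::runif(nc, 3, 240)),
        language = "en",
        stringsAsFactors = FALSE
      )
      cbind(cm, resp)
    })
    out <- rbind(out, careless)
  }
  rownames(out) <- NULL
  raw_items <- vapply(item_cols, function(x) attr(x, "pre_skew"), numeric(n))
  attr(out, "latent_items") <- raw_items
  attr(out, "skewed_items") <- skewed
  out
}

item_scale <- function(map, item) {
  for (v in map) if (item %in% v$items) return(v$scale)
  stopf("item '%s' not in scoring map", item)
}

item_variable <- function(map, item, candidates) {
  for (v in candidates) if (item %in% map[[v]]$items) return(v)
  stopf("item '%s' not owned by any truth variable", item)
}

#' Read / write an item-response table as CSV
#'
#' Plain RFC-4180 CSV with a header row; logical metadata columns are
#' round-tripped as TRUE/FALSE.
#'
#' @param table data frame as produced by [emulate_survey()].
#' @param path file path.
#' @return `write_item_table` returns `path` invisibly; `read_item_table`
#'   returns the data frame.
#' @export
write_item_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_item_table
#' @export
read_item_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  for (col in c("consent", "pain_past_6mo")) {
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  }
  df
}
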