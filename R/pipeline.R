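#' Analysis presets
#'
#' Variable subsets of the two published analyses: `"replication"` (the
#' 6-variable network estimated in two previous large-scale studies) and
#' `"extended"` (the 15 main study variables).
#'
#' @param name `"replication"` or `"extended"`.
#' @return Character vector of variable names.
#' @export
analysis_preset <- function(name = c("replication", "extended")) {
  name <- match.arg(name)
  switch(name,
    replication = c("pain_intensity", "pain_disability", "anxious_symptoms",
                    "depressive_symptoms", "pain_beliefs", "pain_avoidance"),
    extended = c("pain_intensity", "pain_disability", "quality_of_life",
                 "pain_worry", "pain_beliefs", "pain_avoidance",
                 "pain_acceptance", "positive_affect", "mood_symptoms",
                 "stress", "emotional_support", "pain_invalidation",
                 "discrimination", "access_healthcare", "financial_worry")
  )
}

#' Pipeline configuration
#'
#' @param input path to the participant CSV, or a data frame.
#' @param map a `scoring_map` or path to one (YAML/JSON).
#' @param out_dir output directory (created if needed).
#' @param analyses named list of variable subsets; defaults to the
#'   `"replication"` and `"extended"` presets.
#' @param thresholds cleaning thresholds, see [cleaning_thresholds()].
#' @param folds CV folds for estimation.
#' @param bootstrap_B bootstrap replicates per analysis (study value 5000;
#'   set 0 to skip the bootstrap).
#' @param seed master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input, map = default_scoring_map(),
                            out_dir = "painnet-out",
                            analyses = list(
                              replication = analysis_preset("replication"),
                              extended = analysis_preset("extended")),
                            thresholds = cleaning_thresholds(),
                            folds = 10, bootstrap_B = 5000, seed = 1L) {
  if (is.character(map)) map <- read_scoring_map(map)
  for (a in names(analyses)) {
    unknown <- setdiff(analyses[[a]], names(map))
    if (length(unknown)) {
      stopf("configuration error [analysis '%s']: unknown variables %s",
            a, paste(unknown, collapse = ", "))
    }
  }
  structure(list(input = input, map = map, out_dir = out_dir,
                 analyses = analyses, thresholds = thresholds, folds = folds,
                 bootstrap_B = bootstrap_B, seed = seed),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full survey-to-network pipeline
#'
#' Executes clean -> score -> diagnose (Cronbach's alpha, marginal
#' skewness, Henze-Zirkler) -> nonparanormal transform -> estimate ->
#' predictability -> bootstrap for every configured variable subset, and
#' writes all outputs plus a run manifest (settings, seeds, file hashes) to
#' the output directory. Each stage fails fast with a stage-labeled error;
#' the manifest marks the run `complete` only when every stage finished.
#'
#' @param config a [pipeline_config()].
#' @param verbose log stage progress (default TRUE).
#' @return Invisibly, a list with the cleaning report, scored matrix,
#'   diagnostics, and per-analysis results (network, predictability,
#'   bootstrap summary), plus the manifest.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) if (verbose) message(sprintf(...))
  manifest <- list(seed = config$seed, folds = config$folds,
                   bootstrap_B = config$bootstrap_B,
                   package_version = as.character(
                     utils::packageVersion("painnet")),
                   r_version = R.version.string,
                   status = "incomplete", files = list())
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  write_manifest()
  add_file <- function(path) {
    manifest$files[[basename(path)]] <<-
      unname(tools::md5sum(path))
    write_manifest()
  }

  table <- stage("read", {
    if (is.character(config$input)) read_item_table(config$input)
    else config$input
  })

  cleaned <- stage("clean", clean_sample(table, config$map,
                                         config$thresholds))
  log_msg("clean: %d -> %d participants", cleaned$report$n_in,
          cleaned$report$n_out)
  write_cleaning_report(cleaned$report,
                        file.path(config$out_dir, "cleaning_report.json"))
  add_file(file.path(config$out_dir, "cleaning_report.json"))

  scored <- stage("score", score_variables(cleaned$table, config$map))
  write_variable_matrix(scored, file.path(config$out_dir, "variables.csv"))
  add_file(file.path(config$out_dir, "variables.csv"))

  rel <- stage("reliability", reliability_table(cleaned$table, config$map))
  utils::write.csv(rel, file.path(config$out_dir, "reliability.csv"),
                   row.names = FALSE)
  add_file(file.path(config$out_dir, "reliability.csv"))

  results <- list()
  for (a in names(config$analyses)) {
    vars <- config$analyses[[a]]
    sub <- scored[, vars, drop = FALSE]
    sub <- sub[stats::complete.cases(sub), , drop = FALSE]

    diag_raw <- stage("diagnose", list(
      skewness = marginal_skewness(sub),
      henze_zirkler_raw = henze_zirkler(sub)))
    transformed <- stage("transform", nonparanormal_transform(sub))
    diag_raw$henze_zirkler_transformed <- henze_zirkler(transformed)
    utils::write.csv(diag_raw$skewness,
                     file.path(config$out_dir,
                               sprintf("%s_skewness.csv", a)),
                     row.names = FALSE)
    add_file(file.path(config$out_dir, sprintf("%s_skewness.csv", a)))
    log_msg("%s: HZ p raw %.3f, transformed %.3f", a,
            diag_raw$henze_zirkler_raw$p_value,
            diag_raw$henze_zirkler_transformed$p_value)

    net <- stage("estimate", estimate_network(
      transformed, folds = config$folds,
      seed = derive_seed(config$seed, match(a, names(config$analyses)))))
    log_msg("%s: %d nodes, %d edges", a, length(net$labels), net$edge_count)
    for (ext in c("json", "tsv")) {
      f <- file.path(config$out_dir, sprintf("%s_network.%s", a, ext))
      write_network(net, f)
      add_file(f)
    }

    pred <- stage("predictability", predictability(transformed, net))
    f <- file.path(config$out_dir, sprintf("%s_predictability.csv", a))
    utils::write.csv(data.frame(variable = names(pred), r_squared = pred),
                     f, row.names = FALSE)
    add_file(f)

    boot <- NULL
    if (config$bootstrap_B > 0) {
      boot <- stage("bootstrap", bootstrap_network(
        transformed, B = config$bootstrap_B,
        seed = derive_seed(config$seed, 900,
                           match(a, names(config$analyses))),
        folds = config$folds, verbose = verbose))
      f <- file.path(config$out_dir, sprintf("%s_bootstrap.tsv", a))
      write_bootstrap_summary(boot, f)
      add_file(f)
    }
    results[[a]] <- list(diagnostics = diag_raw, network = net,
                         predictability = pred, bootstrap = boot)
  }

  manifest$status <- "complete"
  write_manifest()
  invisible(list(cleaning = cleaned$report, variables = scored,
                 analyses = results, manifest = manifest))
}

#' Run the sample-size simulation from a config file or object
#'
#' Thin wrapper over [run_simulation()] that accepts a
#' [simulation_config()] or a YAML/JSON file with its fields, and writes
#' the result as tidy CSV and JSON.
#'
#' @param config a `simulation_config` or path to a YAML/JSON file.
#' @param out_dir output directory.
#' @param verbose log progress.
#' @return The `simulation_result`, invisibly.
#' @export
run_power_simulation <- function(config, out_dir = "painnet-sim",
                                 verbose = TRUE) {
  if (is.character(config)) config <- read_simulation_config(config)
  res <- run_simulation(config, verbose = verbose)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_simulation_result(res, file.path(out_dir, "simulation.csv"))
  write_simulation_result(res, file.path(out_dir, "simulation.json"))
  invisible(res)
}

#' Read a simulation config from YAML or JSON
#'
#' Recognized fields match the arguments of [simulation_config()].
#'
#' @param path file path.
#' @return A `simulation_config`.
#' @export
read_simulation_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  args <- obj[intersect(names(obj),
                        names(formals(simulation_config)))]
  if (!is.null(args$density_map)) args$density_map <- unlist(args$density_map)
  if (!is.null(args$weight_range)) {
    args$weight_range <- unlist(args$weight_range)
  }
  do.call(simulation_config, args)
}
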