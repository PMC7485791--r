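#' Pipeline configuration
#'
#' A run directory plus everything needed to reproduce a run: the
#' cohort specification, QC/spectral settings, classifier choice, and
#' the root seed. The effective configuration is echoed to
#' `config.json` in the run directory so every artifact is traceable.
#'
#' @param outdir run directory (created if absent).
#' @param seed root seed; also forwarded to the cohort spec when one is
#'   not supplied.
#' @param cohort a [cohort_spec()]; defaults to the study conditions
#'   with this `seed`.
#' @param classifier `"rules"` for the reference rule set, or `"cart"`
#'   to train a CART on the simulated events.
#' @param spectral a [spectral_config()].
#' @param qc a [qc_policy()].
#' @param min_hours daily-inclusion threshold (h).
#' @param log_level `"info"` or `"quiet"`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outdir = tempfile("fatiguerisk_run_"), seed = 1,
                            cohort = cohort_spec(seed = seed),
                            classifier = c("rules", "cart"),
                            spectral = spectral_config(), qc = qc_policy(),
                            min_hours = 3, log_level = c("info", "quiet")) {
  structure(list(outdir = outdir, seed = seed, cohort = cohort,
                 classifier = match.arg(classifier), spectral = spectral,
                 qc = qc, min_hours = min_hours,
                 log_level = match.arg(log_level)),
            class = "pipeline_config")
}

log_msg <- function(config, fmt, ...) {
  if (identical(config$log_level, "info"))
    message(sprintf(paste0("[fatiguerisk] ", fmt), ...))
}

stage_outputs <- function(outdir) {
  file.path(outdir, c(
    simulate = "rri.csv", hrv = "hrv.csv", risk = "daily.csv",
    associate = "results.json"
  )) |> stats::setNames(c("simulate", "hrv", "risk", "associate"))
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order:
#' `simulate` (synthetic cohort to CSV) -> `hrv` (QC + spectra + LF
#' scores) -> `risk` (event classification + daily index) ->
#' `associate` (correlations + median-split test) -> `report`.
#' Each stage reads only the CSV artifacts of its upstream stages, so a
#' stage run out of order fails with an error naming the stage to run
#' first. Rerunning with the same configuration and seed reproduces
#' every numeric output.
#'
#' @param config a [pipeline_config()].
#' @param stages subset of
#'   `c("simulate", "hrv", "risk", "associate", "report")`.
#' @return Invisibly, a list of artifact paths.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("simulate", "hrv", "risk", "associate", "report")) {
  all_stages <- c("simulate", "hrv", "risk", "associate", "report")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  stages <- all_stages[all_stages %in% stages]
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  echo_config(config)
  outs <- stage_outputs(config$outdir)
  need_stage <- function(stage) {
    if (!file.exists(outs[[stage]]))
      stop_("missing upstream artifact '%s': run stage '%s' first",
            basename(outs[[stage]]), stage)
  }

  if ("simulate" %in% stages) {
    log_msg(config, "simulate: %d drivers x %d days (seed %d)",
            config$cohort$n_drivers, config$cohort$n_days, config$cohort$seed)
    cohort <- generate_cohort(config$cohort)
    write_table(cohort_rri_long(cohort), file.path(config$outdir, "rri.csv"), "rri")
    write_table(events_to_long(cohort$events), file.path(config$outdir, "events.csv"), "events")
    write_table(cohort$drivers, file.path(config$outdir, "drivers.csv"), "drivers")
    write_table(cohort$cohort, file.path(config$outdir, "cohort.csv"), "cohort")
    readr::write_csv(cohort$truth$recordings, file.path(config$outdir, "truth_recordings.csv"))
    readr::write_csv(cohort$truth$events, file.path(config$outdir, "truth_events.csv"))
    readr::write_csv(cohort$truth$days, file.path(config$outdir, "truth_days.csv"))
  }

  if ("hrv" %in% stages) {
    need_stage("simulate")
    rri <- read_table(file.path(config$outdir, "rri.csv"), "rri")
    drivers <- read_table(file.path(config$outdir, "drivers.csv"), "drivers")
    log_msg(config, "hrv: %d recordings", nrow(distinct(rri, .data$driver_id, .data$date, .data$condition)))
    hrv <- summarize_hrv(rri_from_long(rri), drivers,
                         cfg = config$spectral, policy = config$qc)
    write_table(hrv, file.path(config$outdir, "hrv.csv"), "hrv")
  }

  if ("risk" %in% stages) {
    need_stage("simulate")
    ev <- events_from_long(read_table(file.path(config$outdir, "events.csv"), "events"))
    cohort_tbl <- read_table(file.path(config$outdir, "cohort.csv"), "cohort")
    classifier <- "rules"
    if (identical(config$classifier, "cart")) {
      feats <- event_features(ev)
      labels <- rule_classify(feats)
      classifier <- train_tree(feats, labels, seed = config$seed)
      write_risk_model(classifier, file.path(config$outdir, "model.json"))
    }
    feats_out <- event_features(ev)
    feats_out$label <- if (identical(classifier, "rules")) rule_classify(feats_out)
                       else predict(classifier, feats_out)
    write_table(feats_out, file.path(config$outdir, "features.csv"), "features")
    daily <- daily_risk_table(ev, cohort_tbl, classifier = classifier,
                              min_hours = config$min_hours)
    log_msg(config, "risk: %d events over %d driver-days", nrow(ev), nrow(daily))
    write_table(daily, file.path(config$outdir, "daily.csv"), "daily")
  }

  if ("associate" %in% stages) {
    need_stage("hrv"); need_stage("risk")
    hrv <- read_table(file.path(config$outdir, "hrv.csv"), "hrv")
    daily <- read_table(file.path(config$outdir, "daily.csv"), "daily")
    cohort_tbl <- read_table(file.path(config$outdir, "cohort.csv"), "cohort")
    records <- build_records(hrv, daily, cohort_tbl)
    readr::write_csv(records, file.path(config$outdir, "analysis_records.csv"))
    res <- run_association(records)
    log_msg(config, "associate: %d analysis-ready records, %d tests",
            res$n_records, res$n_tests)
    payload <- list(
      schema_version = SCHEMA_VERSION, seed = config$seed,
      n_records = res$n_records, n_tests = res$n_tests,
      correlations = lapply(res$correlations, unclass),
      group_comparison = if (!is.null(res$group_comparison)) unclass(res$group_comparison)
    )
    jsonlite::write_json(payload, file.path(config$outdir, "results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  if ("report" %in% stages) {
    need_stage("associate")
    res <- jsonlite::read_json(file.path(config$outdir, "results.json"))
    lines <- c(
      sprintf("fatiguerisk run report (seed %s, schema %s)", res$seed, res$schema_version),
      sprintf("analysis-ready records: %s; statistical tests: %s",
              res$n_records, res$n_tests),
      vapply(names(res$correlations), function(nm) {
        cr <- res$correlations[[nm]]
        if (is.null(cr)) sprintf("  %-22s (not computable)", nm)
        else sprintf("  %-22s r = %+.3f  p = %.4g  n = %d", nm, cr$r, cr$p, cr$n)
      }, character(1)),
      if (!is.null(res$group_comparison)) {
        gc <- res$group_comparison
        sprintf("median split at %.2f events/h: high %.1f (n=%d) vs low %.1f (n=%d), Welch t = %.2f, p = %.4g",
                gc$threshold, gc$mean_high, gc$n_high, gc$mean_low, gc$n_low, gc$t, gc$p)
      }
    )
    writeLines(lines, file.path(config$outdir, "report.txt"))
    log_msg(config, "report: %s", file.path(config$outdir, "report.txt"))
  }

  invisible(as.list(c(outs, report = file.path(config$outdir, "report.txt"))))
}

echo_config <- function(config) {
  cfg <- list(
    schema_version = SCHEMA_VERSION, seed = config$seed,
    classifier = config$classifier, min_hours = config$min_hours,
    cohort = unclass(config$cohort)[setdiff(names(config$cohort), "norms")],
    spectral = unclass(config$spectral), qc = unclass(config$qc)
  )
  jsonlite::write_json(cfg, file.path(config$outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Top-level keys mirror [pipeline_config()] arguments; the `cohort`,
#' `spectral` and `qc` keys take the corresponding constructor
#' arguments as nested maps. Omitted keys keep their defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @param ... overrides applied after the file (e.g. `seed`, `outdir`).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  over <- list(...)
  raw <- modifyList(raw %||% list(), over)
  seed <- raw$seed %||% 1
  cohort_args <- raw$cohort %||% list()
  if (is.null(cohort_args$seed)) cohort_args$seed <- seed
  if (!is.null(cohort_args$age_range)) cohort_args$age_range <- unlist(cohort_args$age_range)
  pipeline_config(
    outdir = raw$outdir %||% tempfile("fatiguerisk_run_"),
    seed = seed,
    cohort = do.call(cohort_spec, cohort_args),
    classifier = raw$classifier %||% "rules",
    spectral = do.call(spectral_config, raw$spectral %||% list()),
    qc = do.call(qc_policy, raw$qc %||% list()),
    min_hours = raw$min_hours %||% 3,
    log_level = raw$log_level %||% "info"
  )
}
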