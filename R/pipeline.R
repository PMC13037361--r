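# End-to-end pipeline: simulate -> filter -> build scenarios ->
# cross-validate -> report, as one seeded, fully configured run.

#' Configuration of a full pipeline run
#'
#' A run is fully specified by its configuration: the generator and model
#' configurations, the scenario selection, the fold count and one global
#' seed from which every stage seed is derived deterministically
#' (generator: `seed`; scenario s assembly: `seed + 100 * s`;
#' cross-validation of scenario s: `seed + 1000 * s`), so stages can be
#' rerun in isolation.
#'
#' @param generator A [synthetic_config()]; its seed is overridden by
#'   `seed`.
#' @param model A [model_config()].
#' @param scenarios Subset of `1:3`.
#' @param k Cross-validation folds.
#' @param seed Global integer seed.
#'
#' @return An object of class `run_config`.
#' @export
run_config <- function(generator = synthetic_config(),
                       model = model_config(),
                       scenarios = 1:3,
                       k = 5,
                       seed = 1L) {
  stopifnot(inherits(generator, "synthetic_config"),
            inherits(model, "model_config"),
            all(scenarios %in% 1:3), length(scenarios) >= 1)
  generator$seed <- as.integer(seed)
  structure(list(generator = generator, model = model,
                 scenarios = sort(unique(as.integer(scenarios))),
                 k = as.integer(k), seed = as.integer(seed)),
            class = "run_config")
}

run_config_as_list <- function(config) {
  list(generator = unclass(config$generator),
       model = unclass(config$model),
       scenarios = config$scenarios, k = config$k, seed = config$seed)
}

#' Execute a full pipeline run
#'
#' Generates the synthetic cohort, applies the eligibility filters, builds
#' every selected scenario, cross-validates the classifier on each, and
#' writes all artifacts under `out_dir`: the verbatim run configuration
#' (`run_config.yaml`, with an MD5 hash of its content recorded in the
#' log), the cohort CSV and its generator sidecar, a provenance file with
#' counts at every step, and per scenario the labelled dataset, the
#' per-fold metric table, the row-normalized best-fold confusion matrix
#' and a structured summary. A stage failure aborts with the stage name;
#' an existing non-empty `out_dir` is refused so reruns never mutate
#' prior runs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created; must not already contain a
#'   run).
#' @param quiet Suppress progress messages.
#'
#' @return Invisibly, a list with the cohort, the filter log, and one
#'   `list(dataset, cv)` per scenario.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0) {
    stop("`out_dir` already contains files; refusing to overwrite a ",
         "previous run", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  say <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   paste0(...))
    cat(msg, "\n", file = log_path, append = TRUE)
    if (!quiet) message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  cfg_path <- file.path(out_dir, "run_config.yaml")
  yaml::write_yaml(run_config_as_list(config), cfg_path)
  say("run config written (md5 ", unname(tools::md5sum(cfg_path)), ")")

  cohort <- stage("simulate", generate_population(config$generator))
  write_cohort(cohort, file.path(out_dir, "cohort.csv"), config$generator)
  say("simulated ", nrow(cohort), " participants")

  fv <- stage("filter", filter_valid(cohort))
  say("filter kept ", nrow(fv$kept), " of ", nrow(cohort),
      " (", nrow(fv$rejections), " rejected)")

  results <- list()
  provenance <- list(
    n_simulated = nrow(cohort),
    n_kept = nrow(fv$kept),
    rejections = as.list(table(fv$rejections$reason))
  )
  for (s in config$scenarios) {
    sdir <- file.path(out_dir, paste0("scenario_", s))
    dir.create(sdir, showWarnings = FALSE)
    ds <- stage(paste0("build_scenario_", s),
                build_scenario(fv$kept, s, seed = config$seed + 100L * s))
    say("scenario ", s, ": ", sum(ds$labels == 0), " vs ",
        sum(ds$labels == 1))
    out <- cbind(ds$data, label = ds$labels)
    utils::write.csv(out, file.path(sdir, "dataset.csv"),
                     row.names = FALSE, na = "")
    cv <- stage(paste0("evaluate_scenario_", s),
                cross_validate(ds, config$model, k = config$k,
                               seed = config$seed + 1000L * s))
    utils::write.csv(cv$metrics, file.path(sdir, "metrics_folds.csv"),
                     row.names = FALSE)
    best_conf <- normalize_confusion(cv$folds[[cv$best_fold]]$confusion)
    utils::write.csv(as.data.frame(best_conf),
                     file.path(sdir, "confusion_best_normalized.csv"),
                     row.names = TRUE)
    yaml::write_yaml(list(
      scenario = s,
      counts = as.list(ds$provenance$counts),
      mean = as.list(cv$mean),
      sd = as.list(cv$sd),
      best_fold = cv$best_fold,
      chi_squared = cv$chi_squared,
      proportion_test = cv$proportion_test,
      t_test = cv$t_test
    ), file.path(sdir, "summary.yaml"))
    say("scenario ", s, " cross-validated: accuracy ",
        sprintf("%.3f", cv$mean[["accuracy"]]), ", AUC ",
        sprintf("%.3f", cv$mean[["auc_macro"]]))
    provenance[[paste0("scenario_", s)]] <-
      as.list(ds$provenance$counts)
    results[[paste0("scenario_", s)]] <- list(dataset = ds, cv = cv)
  }
  yaml::write_yaml(provenance, file.path(out_dir, "provenance.yaml"))
  say("run complete")
  invisible(list(cohort = cohort, filter = fv, scenarios = results,
                 out_dir = out_dir))
}

#' Assemble a human-readable run report
#'
#' Reads a completed run directory and writes `report.txt`: the
#' participant-flow counts, group-mean diurnal activity curves per
#' scenario, the row-normalized best-fold confusion matrices and the
#' metric table as mean +/- SD rows. Scenarios absent from the run are
#' marked "not run"; missing required artifacts abort with an explicit
#' listing.
#'
#' @param run_dir A directory written by [run_pipeline()].
#' @return The report text, invisibly; `report.txt` is written inside
#'   `run_dir`.
#' @export
make_report <- function(run_dir) {
  required <- c("run_config.yaml", "provenance.yaml", "cohort.csv")
  missing <- required[!file.exists(file.path(run_dir, required))]
  if (length(missing)) {
    stop("cannot assemble report; missing artifacts: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  prov <- yaml::read_yaml(file.path(run_dir, "provenance.yaml"))
  lines <- c("Diurnal activity KOA classification - run report",
             strrep("=", 48), "",
             "Participant flow",
             sprintf("  simulated: %d", prov$n_simulated),
             sprintf("  after eligibility filters: %d", prov$n_kept))
  for (r in names(prov$rejections)) {
    lines <- c(lines, sprintf("    rejected (%s): %d", r,
                              prov$rejections[[r]]))
  }
  scenario_names <- c("Healthy vs KOA",
                      "Prodromal vs Diagnosed",
                      "Healthy vs Prodromal (5y)")
  metric_rows <- character(0)
  for (s in 1:3) {
    sdir <- file.path(run_dir, paste0("scenario_", s))
    lines <- c(lines, "", sprintf("Scenario %d: %s", s, scenario_names[s]))
    if (!file.exists(file.path(sdir, "summary.yaml"))) {
      lines <- c(lines, "  not run")
      next
    }
    summ <- yaml::read_yaml(file.path(sdir, "summary.yaml"))
    dat <- utils::read.csv(file.path(sdir, "dataset.csv"))
    lines <- c(lines,
               sprintf("  classes: %d vs %d", sum(dat$label == 0),
                       sum(dat$label == 1)),
               "  mean diurnal activity by class (hour 0..23):")
    for (lb in 0:1) {
      prof <- colMeans(as.matrix(dat[dat$label == lb, HOUR_COLS]))
      lines <- c(lines, sprintf("    class %d: %s", lb,
                                paste(sprintf("%.1f", prof),
                                      collapse = " ")))
    }
    conf <- utils::read.csv(
      file.path(sdir, "confusion_best_normalized.csv"), row.names = 1)
    lines <- c(lines, "  best-fold normalized confusion (rows = true):",
               sprintf("    true 0: %.3f %.3f", conf[1, 1], conf[1, 2]),
               sprintf("    true 1: %.3f %.3f", conf[2, 1], conf[2, 2]))
    metric_rows <- c(metric_rows, sprintf(
      "  %-28s %5.1f +/- %4.1f%%   %.3f +/- %.3f   %.3f +/- %.3f   %.3f +/- %.3f",
      scenario_names[s],
      100 * summ$mean$accuracy, 100 * summ$sd$accuracy,
      summ$mean$f1_macro, summ$sd$f1_macro,
      summ$mean$sensitivity_macro, summ$sd$sensitivity_macro,
      summ$mean$auc_macro, summ$sd$auc_macro))
  }
  lines <- c(lines, "",
             "Cross-validation metrics (mean +/- SD over folds)",
             paste0("  ", sprintf("%-28s", "scenario"),
                    " accuracy          F1 (macro)        ",
                    "sensitivity (macro)  AUC (macro)"),
             metric_rows, "")
  text <- paste(lines, collapse = "\n")
  writeLines(text, file.path(run_dir, "report.txt"))
  invisible(text)
}
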