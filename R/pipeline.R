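#' Read a pipeline configuration file
#'
#' YAML or JSON configuration with optional blocks `growth_law`,
#' `generator`, `phosphorelay`, `colony`, `run` (seed, strain,
#' inducer level/time). Unknown top-level keys are rejected.
#'
#' @param path file path (`.yaml`/`.yml`/`.json`).
#' @return named list of class `run_config`.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  known <- c("growth_law", "generator", "phosphorelay", "colony", "run")
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0)
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  structure(cfg, class = "run_config")
}

# build typed objects from config blocks (missing blocks -> defaults)
config_objects <- function(cfg) {
  list(
    law = do.call(growth_law, as.list(cfg$growth_law %||% list())),
    gen = do.call(generator_config, as.list(cfg$generator %||% list())),
    params = do.call(phosphorelay_params, as.list(cfg$phosphorelay %||% list())),
    colony = do.call(colony_model, as.list(cfg$colony %||% list())),
    run = cfg$run %||% list()
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_table_with_meta <- function(df, path, seed, what) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# growthrelay %s v%s seed=%s", what,
                     as.character(utils::packageVersion("growthrelay")),
                     format(seed)), con)
  utils::write.csv(as.data.frame(df), con, row.names = FALSE)
  invisible(path)
}

#' Run one pipeline stage
#'
#' Stage commands binding the package end to end, each writing CSV tables
#' (with a one-line `#` metadata header carrying the seed) plus a JSON run
#' manifest into `out_dir`:
#' \describe{
#'   \item{generate}{sample a lineage and render its time-lapse traces.}
#'   \item{simulate}{phosphorelay run for the configured strain over a
#'     declining growth trajectory; writes the state time series and the
#'     per-cycle pulse table.}
#'   \item{analyze}{quantify previously generated traces into per-cycle
#'     records.}
#'   \item{classify}{fit the growth-rate fate threshold and ROC on the
#'     records.}
#'   \item{deferral}{per-generation predicted vs observed sporulating
#'     fractions.}
#' }
#' Stages read their upstream tables from `out_dir`; a missing input names
#' the producing command in the error.
#'
#' @param command stage name.
#' @param config a [read_config()] result or config list; `NULL` for
#'   defaults.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed overriding the config seed.
#' @return named list of written file paths, invisibly.
#' @export
run_pipeline <- function(command = c("generate", "simulate", "analyze",
                                     "classify", "deferral"),
                         config = NULL, out_dir = tempfile("growthrelay-"),
                         seed = NULL) {
  command <- match.arg(command)
  ob <- config_objects(config %||% list())
  if (!is.null(seed)) ob$gen$seed <- as.integer(seed)
  seed <- ob$gen$seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  need <- function(f, producer) {
    p <- file.path(out_dir, f)
    if (!file.exists(p))
      stop(sprintf("missing %s: run the `%s` stage first", f, producer))
    utils::read.csv(p, comment.char = "#")
  }

  if (command == "generate") {
    tree <- sample_lineage(ob$gen, ob$law)
    traces <- render_timelapse(tree, ob$gen, ob$law)
    paths$lineage <- write_table_with_meta(tree,
      file.path(out_dir, "lineage.csv"), seed, "lineage")
    paths$traces <- write_table_with_meta(traces,
      file.path(out_dir, "traces.csv"), seed, "traces")
  } else if (command == "simulate") {
    run <- ob$run
    strain <- strain_config(run$strain %||% "WT",
                            inducer_level = run$inducer_level %||% 1,
                            inducer_at = run$inducer_at %||% 0)
    traj <- growth_trajectory(mu = run$mu %||% c(0.6, 0.1),
                              time = run$mu_time %||% c(0, 30),
                              duration = run$duration %||% 30)
    sim <- simulate_phosphorelay(strain, ob$params, traj, law = ob$law)
    pulses <- pulse_amplitudes(sim)
    paths$timeseries <- write_table_with_meta(sim,
      file.path(out_dir, "phosphorelay_timeseries.csv"), seed, "timeseries")
    paths$pulses <- write_table_with_meta(pulses,
      file.path(out_dir, "pulse_amplitudes.csv"), seed, "pulses")
  } else if (command == "analyze") {
    traces <- need("traces.csv", "generate")
    lineage <- need("lineage.csv", "generate")
    records <- analyze_timelapse(traces, lineage)
    records <- merge(records,
                     lineage[, c("cell_id", "birth_time", "end_time")],
                     by = "cell_id")
    paths$records <- write_table_with_meta(records,
      file.path(out_dir, "cycle_records.csv"), seed, "records")
  } else if (command == "classify") {
    records <- need("cycle_records.csv", "analyze")
    fit <- fit_logistic(records, "mean_mu")
    thr <- threshold_from_fit(fit)
    roc <- roc_curve(records$fate, records$mean_mu, direction = "below")
    paths$threshold <- write_table_with_meta(
      data.frame(predictor = "mean_mu", threshold = thr$threshold,
                 se = thr$standard_error, direction = thr$direction,
                 auc = roc$auc, n = fit$n),
      file.path(out_dir, "threshold.csv"), seed, "threshold")
    paths$roc <- write_table_with_meta(roc$sweep,
      file.path(out_dir, "roc.csv"), seed, "roc")
  } else if (command == "deferral") {
    records <- need("cycle_records.csv", "analyze")
    thr_tab <- need("threshold.csv", "classify")
    def <- predict_deferral(records, thr_tab$threshold[1])
    paths$deferral <- write_table_with_meta(def,
      file.path(out_dir, "deferral.csv"), seed, "deferral")
  }

  manifest <- list(command = command, seed = seed,
                   package = "growthrelay",
                   version = as.character(utils::packageVersion("growthrelay")),
                   files = lapply(paths, basename),
                   config_hash = sum(utf8ToInt(paste(
                     deparse(config %||% list()), collapse = ""))))
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0(command, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
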