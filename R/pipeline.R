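# End-to-end orchestration: simulate (or read) -> reduce -> fit -> in-vivo
# metrics -> allometric classification -> dilatation correlations.

#' Run configuration for the analysis pipeline
#'
#' Exactly one of `input` (paths to the raw-data and metadata CSVs) or
#' `simulate` (arguments forwarded to [simulate_cohort()]) must be given.
#'
#' @param input List with `data_file`, `metadata_file`, or `NULL`.
#' @param simulate List of [simulate_cohort()] arguments, or `NULL`.
#' @param seed Master seed, recorded in the manifest and used for every
#'   stochastic stage.
#' @param fit A [fit_config()]; its seed is derived from `seed` unless set
#'   explicitly.
#' @param interval_level Allometric classification interval level.
#' @param out_dir Output directory for tables and JSON, or `NULL` to skip
#'   writing.
#' @return List of class `run_config`.
#' @export
run_config <- function(input = NULL, simulate = NULL, seed = 1L,
                       fit = fit_config(seed = seed), interval_level = 0.95,
                       out_dir = NULL) {
  if (is.null(input) == is.null(simulate))
    stop("run_config: provide exactly one of input or simulate")
  structure(list(input = input, simulate = simulate, seed = as.integer(seed),
                 fit = fit, interval_level = interval_level,
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose top-level keys mirror the [run_config()]
#'   arguments (`fit` as a list of [fit_config()] arguments).
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("read_run_config: the yaml package is required to read config files")
  cfg <- yaml::read_yaml(path)
  fit <- if (is.null(cfg$fit)) fit_config(seed = cfg$seed %||% 1L)
         else do.call(fit_config, cfg$fit)
  run_config(input = cfg$input, simulate = cfg$simulate,
             seed = cfg$seed %||% 1L, fit = fit,
             interval_level = cfg$interval_level %||% 0.95,
             out_dir = cfg$out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Stages, in order: obtain subject records (simulation or CSV input);
#' estimate each subject's in-vivo axial stretch; fit the eight-parameter
#' model per subject; compute in-vivo metrics at 80/120 mmHg; fit the
#' allometric model on the wild-type samples and classify every vessel;
#' correlate each metric with the normalized diameter. Per-sample failures
#' are logged and skipped (the sample appears in `failures` instead of the
#' metrics table); configuration errors abort.
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages.
#' @return List of class `pipeline_result`: `metrics` (cohort table with
#'   classification columns), `fits`, `allometric_model`, `correlations`,
#'   `failures` (data frame sample_id/stage/reason), `manifest` (seed,
#'   package version, counts), and `ok` (TRUE when no sample failed).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  if (!is.null(config$input)) {
    records <- read_cohort(config$input$data_file, config$input$metadata_file,
                           quiet = quiet)
  } else {
    sim_args <- config$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    cohort <- do.call(simulate_cohort, sim_args)
    records <- cohort$records
    if (is.null(records))
      stop("run_pipeline: simulate must produce records (records = TRUE)")
  }
  say("pipeline: ", length(records), " subject records")

  failures <- data.frame(sample_id = character(), stage = character(),
                         reason = character(), stringsAsFactors = FALSE)
  fail <- function(id, stage, e) {
    failures <<- rbind(failures, data.frame(
      sample_id = id, stage = stage, reason = conditionMessage(e),
      stringsAsFactors = FALSE))
    say("  [", id, "] failed at ", stage, ": ", conditionMessage(e))
  }

  fits <- list(); metrics <- NULL
  for (r in records) {
    lam_z_iv <- tryCatch(estimate_invivo_stretch(r), error = function(e) {
      fail(r$id, "invivo_stretch", e); NULL })
    if (is.null(lam_z_iv)) next
    fit <- tryCatch(fit_parameters(r, config$fit), error = function(e) {
      fail(r$id, "fit", e); NULL })
    if (is.null(fit)) next
    m <- tryCatch(compute_invivo_metrics(fit, r, lam_z_iv = lam_z_iv),
                  error = function(e) { fail(r$id, "metrics", e); NULL })
    if (is.null(m)) next
    fits[[r$id]] <- fit
    class(m) <- "data.frame"
    metrics <- rbind(metrics, m)
  }
  if (is.null(metrics))
    stop("run_pipeline: no sample passed the fitting stage")
  rownames(metrics) <- NULL

  wt <- metrics[metrics$genotype == "WT", ]
  model <- NULL; correlations <- NULL
  if (nrow(wt) >= 3) {
    model <- fit_allometric(wt$body_mass_g, wt$di_sys,
                            interval_level = config$interval_level)
    cls <- classify_vessel(model, metrics$body_mass_g, metrics$di_sys)
    metrics$normalized_diameter <- cls$normalized_diameter
    metrics$status <- cls$status
    metrics$small <- cls$small
    correlations <- tryCatch(correlate_with_dilatation(metrics),
                             error = function(e) { say("  correlations skipped: ",
                                                       conditionMessage(e)); NULL })
  } else {
    say("pipeline: < 3 WT samples - allometric stage skipped")
  }

  manifest <- list(seed = config$seed,
                   package = as.character(packageVersion("aortamech")),
                   n_records = length(records), n_fitted = length(fits),
                   n_failed = nrow(failures))
  res <- structure(list(metrics = metrics, fits = fits,
                        allometric_model = model,
                        correlations = correlations, failures = failures,
                        manifest = manifest, ok = nrow(failures) == 0),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) .write_pipeline_outputs(res, config$out_dir)
  res
}

.write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(res$metrics, file.path(out_dir, "cohort_metrics.csv"),
            row.names = FALSE)
  if (!is.null(res$correlations))
    write.csv(res$correlations, file.path(out_dir, "correlations.csv"),
              row.names = FALSE)
  if (!is.null(res$allometric_model))
    write_allometric_json(res$allometric_model,
                          file.path(out_dir, "allometric_model.json"))
  for (id in names(res$fits))
    write_fit_json(res$fits[[id]], file.path(out_dir, paste0("fit_", id, ".json")))
  if (nrow(res$failures))
    write.csv(res$failures, file.path(out_dir, "failures.csv"),
              row.names = FALSE)
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline result: %d/%d samples fitted, %d failures\n",
              x$manifest$n_fitted, x$manifest$n_records, x$manifest$n_failed))
  if (!is.null(x$allometric_model)) print(x$allometric_model)
  if (!is.null(x$correlations)) {
    cat("Correlations with normalized diameter:\n")
    print(x$correlations, row.names = FALSE)
  }
  invisible(x)
}
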