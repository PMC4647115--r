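# End-to-end orchestration: simulate -> curate -> SVM-RFE -> oPLS-DA
# validation -> univariate summaries (-> mass annotation when an
# annotation table is supplied), persisting every intermediate and a
# manifest with checksums so a run is a pure function of its config.

#' Pipeline run configuration
#'
#' One global seed governs every stochastic stage (simulation,
#' random-subset CV, permutations). The configuration round-trips
#' losslessly through JSON.
#'
#' @param synthetic a [synthetic_config()]; its seed is overridden by
#'   `seed`.
#' @param min_runs,fraction,multiple curation parameters (see [curate()]).
#' @param cost SVM regularization constant.
#' @param scaling_mode `"global"` or `"fold"` autoscaling for RFE.
#' @param n_ortho oPLS-DA orthogonal components (`NULL` = select by LOO
#'   Q2).
#' @param n_perm label permutations for the validation stage.
#' @param annotations optional `data.frame` for [annotate_masses()]
#'   (columns `observed_mz`, `formula`, `ion`).
#' @param out_dir output directory (created); defaults to a fresh
#'   temporary directory.
#' @param seed global RNG seed.
#' @return A `run_config` list.
#' @export
run_config <- function(synthetic = synthetic_config(), min_runs = 40,
                       fraction = 0.5, multiple = 10, cost = 1,
                       scaling_mode = "global", n_ortho = NULL,
                       n_perm = 99, annotations = NULL, out_dir = NULL,
                       seed = 1) {
  stopifnot(inherits(synthetic, "synthetic_config"))
  synthetic$seed <- seed
  cfg <- list(synthetic = synthetic, min_runs = min_runs,
              fraction = fraction, multiple = multiple, cost = cost,
              scaling_mode = scaling_mode, n_ortho = n_ortho,
              n_perm = n_perm, annotations = annotations,
              out_dir = out_dir, seed = seed)
  structure(cfg, class = "run_config")
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  cfg$synthetic <- unclass(cfg$synthetic)
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}

#' Run the full discovery pipeline
#'
#' Executes, in order: synthetic-data simulation, curation, nested-LOOCV
#' SVM-RFE panel selection, oPLS-DA validation of the selected panel,
#' univariate feature summaries, and (when configured) mass annotation.
#' Every intermediate is written under `out_dir` as CSV/JSON, including a
#' panel-size-versus-metrics table (the accuracy-evolution curve) and a
#' per-sample score-versus-age table. A manifest records the config hash,
#' per-file checksums, stage wall times and warnings; identical configs
#' reproduce identical checksums.
#'
#' @param config a [run_config()].
#' @param verbose print stage progress.
#' @return A `run_manifest`.
#' @export
run_pipeline <- function(config = run_config(), verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  # validate before any stage runs
  stopifnot(inherits(config$synthetic, "synthetic_config"))
  if (config$cost <= 0) stop("cost must be positive")
  out_dir <- config$out_dir %||% tempfile("ocmetab_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  files <- character(0)
  timings <- numeric(0)
  warnings_log <- character(0)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e)
        stop("stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)),
      warning = function(w) {
        warnings_log <<- c(warnings_log,
                           paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    say("stage %-10s done (%.1fs)", name, timings[[name]])
    res
  }
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    files <<- c(files, path)
    path
  }

  sim <- stage("simulate", simulate_run_table(config$synthetic))
  emit("run_table.csv", function(p) write_run_table(sim$table, p))
  emit("ground_truth.json", function(p) write_ground_truth(sim$truth, p))

  cur <- stage("curate", curate(sim$table, min_runs = config$min_runs,
                                fraction = config$fraction,
                                multiple = config$multiple))
  emit("sample_matrix.csv", function(p)
    write.csv(data.frame(cur$matrix$samples,
                         cur$matrix$x, check.names = FALSE),
              p, row.names = FALSE))
  emit("curation_report.json", function(p)
    jsonlite::write_json(unclass(cur$report), p, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE))

  fit <- stage("rfe", svm_rfe(cur$matrix, cost = config$cost,
                              scaling_mode = config$scaling_mode))
  emit("rfe_trace.csv", function(p)
    write.csv(summary(fit$trace), p, row.names = FALSE))
  emit("model.json", function(p)
    jsonlite::write_json(list(feature_ids = fit$model$feature_ids,
                              w = fit$model$w, b = fit$model$b,
                              cost = fit$model$cost,
                              scaling = fit$model$scaling),
                         p, auto_unbox = TRUE, digits = NA, pretty = TRUE))
  # per-sample held-out score vs age (hyperplane-projection table)
  emit("scores.csv", function(p) {
    sc <- fit$loocv
    age <- cur$matrix$samples$age[match(names(sc$scores),
                                        cur$matrix$samples$sample_id)]
    write.csv(data.frame(sample_id = names(sc$scores), score = sc$scores,
                         predicted = sc$predicted, true = sc$truth,
                         age = age, row.names = NULL),
              p, row.names = FALSE)
  })

  panel_matrix <- select_features(cur$matrix, fit$panel$features)
  val <- stage("validate", oplsda_validate(panel_matrix,
                                           n_ortho = config$n_ortho,
                                           n_perm = config$n_perm,
                                           seed = config$seed + 1L))
  emit("oplsda_validation.json", function(p)
    jsonlite::write_json(list(R2Y = val$R2Y, n_ortho = val$n_ortho,
                              Q2 = as.list(val$Q2),
                              permutation_p = val$permutation$p_value,
                              n_perm = config$n_perm),
                         p, auto_unbox = TRUE, digits = NA, pretty = TRUE))

  summ <- stage("summarize", feature_summaries(cur$matrix,
                                               fit$panel$features))
  emit("feature_summaries.csv", function(p)
    write.csv(summ, p, row.names = FALSE))

  if (!is.null(config$annotations)) {
    ann <- stage("annotate", annotate_masses(config$annotations))
    emit("mass_annotation.csv", function(p)
      write.csv(ann, p, row.names = FALSE))
  }

  manifest <- structure(list(
    config_hash = .config_hash(config),
    seed = config$seed,
    out_dir = out_dir,
    files = setNames(as.character(tools::md5sum(files)), basename(files)),
    selected_panel = fit$panel$features,
    panel_size = fit$panel$size,
    panel_metrics = c(accuracy = fit$panel$accuracy,
                      sensitivity = fit$panel$sensitivity,
                      specificity = fit$panel$specificity),
    full_model_metrics = fit$full_loocv,
    oplsda = list(R2Y = val$R2Y, Q2 = val$Q2,
                  permutation_p = val$permutation$p_value),
    stage_seconds = timings,
    warnings = warnings_log,
    versions = c(ocmetab = as.character(utils::packageVersion("ocmetab")),
                 R = paste(R.version$major, R.version$minor, sep = "."))
  ), class = "run_manifest")
  mpath <- emit("manifest.json", function(p)
    jsonlite::write_json(unclass(manifest), p, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE))
  manifest$files <- c(manifest$files,
                      manifest.json = unname(tools::md5sum(mpath)))
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Pipeline run manifest\n")
  cat("  config hash:", x$config_hash, "\n")
  cat(sprintf("  selected panel: %d features; accuracy %.1f%% (full model %.1f%%)\n",
              x$panel_size, x$panel_metrics["accuracy"],
              x$full_model_metrics["accuracy"]))
  cat(sprintf("  oPLS-DA R2Y %.3f, loo Q2 %.3f, permutation p %.3g\n",
              x$oplsda$R2Y, x$oplsda$Q2[["loo"]], x$oplsda$permutation_p))
  cat("  outputs:", length(x$files), "files in", x$out_dir, "\n")
  invisible(x)
}
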