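# Nested-LOOCV recursive feature elimination: at each panel size, run full
# LOOCV, average each feature's SVM weight over the fold models, record the
# metrics, and discard the least important feature (smallest |average
# weight|). The minimal optimal panel is the smallest size at which
# (accuracy, sensitivity, specificity) is jointly maximal.

#' Recursive feature elimination with nested LOOCV
#'
#' Iterates panel sizes J, J-1, ..., 1. At each size the current panel is
#' evaluated by leave-one-out cross-validation; each feature's weight is
#' averaged across the n fold models, and the feature with the smallest
#' absolute average weight is eliminated (ties broken by the
#' earliest-indexed feature, so reruns are deterministic).
#'
#' In the default `"global"` scaling mode the matrix is autoscaled once
#' before elimination begins; `"fold"` mode rescales within every training
#' fold (slower, leakage-free).
#'
#' @param x a [sample_matrix()], or a matrix with `y`.
#' @param y class labels when `x` is a bare matrix.
#' @param cost SVM regularization constant.
#' @param scaling_mode `"global"` (default) or `"fold"`.
#' @param min_size smallest panel size to evaluate (default 1).
#' @param importance `"signed_mean"` (default: absolute value of the
#'   fold-averaged signed weight) or `"mean_abs"` (fold-average of
#'   absolute weights).
#' @param tol SMO tolerance for the fold models.
#' @param verbose print progress every 25 steps.
#' @return An `rfe_trace`: `data.frame`-like record with one step per
#'   panel size (`size`, `accuracy`, `sensitivity`, `specificity`,
#'   `eliminated`) plus per-step active feature ids and average weights.
#' @export
rfe <- function(x, y = NULL, cost = 1, scaling_mode = c("global", "fold"),
                min_size = 1, importance = c("signed_mean", "mean_abs"),
                tol = 1e-4, verbose = FALSE) {
  d <- .as_xy(x, y)
  scaling_mode <- match.arg(scaling_mode)
  importance <- match.arg(importance)
  J <- ncol(d$x)
  if (J < 2) stop("recursive elimination needs at least 2 features")
  if (min_size < 1 || min_size > J) stop("min_size must lie in [1, J]")

  xs <- if (scaling_mode == "global") autoscale(d$x)$x else d$x
  active <- colnames(xs)
  n <- nrow(xs)
  sizes <- seq(J, min_size)
  steps <- vector("list", length(sizes))

  for (k in seq_along(sizes)) {
    xa <- xs[, active, drop = FALSE]
    if (scaling_mode == "global") {
      res <- cpp_svm_loocv(xa, d$y, cost, tol)
      scores <- res$scores
      avg_w <- setNames(res$avg_w, active)
      if (importance == "mean_abs") imp <- setNames(res$avg_abs_w, active)
    } else {
      scores <- numeric(n)
      avg_w <- setNames(numeric(length(active)), active)
      abs_w <- avg_w
      for (i in seq_len(n)) {
        m <- train_linear_svm(xa[-i, , drop = FALSE], d$labels[-i],
                              cost = cost, tol = tol)
        scores[i] <- metabolic_score(m, xa[i, , drop = FALSE])$score
        avg_w <- avg_w + m$w / n
        abs_w <- abs_w + abs(m$w) / n
      }
      if (importance == "mean_abs") imp <- abs_w
    }
    if (importance == "signed_mean") imp <- abs(avg_w)
    predicted <- ifelse(scores > 0, "C", "N")
    metrics <- .binary_metrics(d$labels, predicted)
    drop_id <- if (length(active) > min_size)
      active[which.min(imp)] else NA_character_
    steps[[k]] <- list(size = length(active), features = active,
                       avg_w = avg_w,
                       accuracy = metrics[["accuracy"]],
                       sensitivity = metrics[["sensitivity"]],
                       specificity = metrics[["specificity"]],
                       eliminated = drop_id)
    if (verbose && k %% 25 == 0)
      message(sprintf("  RFE step %d/%d (size %d): accuracy %.1f%%",
                      k, length(sizes), length(active),
                      metrics[["accuracy"]]))
    if (!is.na(drop_id)) active <- setdiff(active, drop_id)
  }
  structure(list(steps = steps, cost = cost, scaling_mode = scaling_mode,
                 importance = importance, n_samples = n),
            class = "rfe_trace")
}

#' Summarise an RFE trace as a data frame
#'
#' One row per elimination step: panel size, LOOCV metrics and the feature
#' eliminated after the step — the panel-size versus accuracy curve.
#'
#' @param object an `rfe_trace`.
#' @param ... unused.
#' @return `data.frame` with columns `size`, `accuracy`, `sensitivity`,
#'   `specificity`, `eliminated`.
#' @export
summary.rfe_trace <- function(object, ...) {
  do.call(rbind, lapply(object$steps, function(s)
    data.frame(size = s$size, accuracy = s$accuracy,
               sensitivity = s$sensitivity, specificity = s$specificity,
               eliminated = s$eliminated, stringsAsFactors = FALSE)))
}

#' @export
print.rfe_trace <- function(x, ...) {
  df <- summary(x)
  cat(sprintf("SVM-RFE trace: %d -> %d features (%s scaling, cost %g)\n",
              max(df$size), min(df$size), x$scaling_mode, x$cost))
  best <- select_optimal_panel(x)
  cat(sprintf("  optimal panel: %d features, accuracy %.1f%% / sens %.1f%% / spec %.1f%%\n",
              best$size, best$accuracy, best$sensitivity, best$specificity))
  invisible(x)
}

#' Select the minimal optimal panel from an RFE trace
#'
#' Among all elimination steps, finds the lexicographic maximum of
#' (accuracy, sensitivity, specificity) and returns the smallest panel
#' achieving it — the "minimum of N features" semantics.
#'
#' @param trace an `rfe_trace`.
#' @return A `panel_selection` with `features`, `size`, `accuracy`,
#'   `sensitivity`, `specificity`.
#' @export
select_optimal_panel <- function(trace) {
  stopifnot(inherits(trace, "rfe_trace"))
  df <- summary(trace)
  if (is.null(df) || nrow(df) == 0) stop("empty trace")
  best <- df[order(-df$accuracy, -df$sensitivity, -df$specificity,
                   df$size), ][1, ]
  step <- trace$steps[[which(vapply(trace$steps, `[[`, 0, "size") ==
                               best$size)[1]]]
  structure(list(features = step$features, size = best$size,
                 accuracy = best$accuracy, sensitivity = best$sensitivity,
                 specificity = best$specificity,
                 avg_w = step$avg_w),
            class = "panel_selection")
}

#' @export
print.panel_selection <- function(x, ...) {
  cat(sprintf(
    "Selected panel: %d features (accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%)\n",
    x$size, x$accuracy, x$sensitivity, x$specificity))
  cat("  ", paste(x$features, collapse = ", "), "\n")
  invisible(x)
}

#' Fit the full SVM-RFE panel-selection workflow
#'
#' The flagship fitting function: runs nested-LOOCV recursive feature
#' elimination, selects the minimal optimal panel, and refits the final
#' linear SVM (with its metabolic-score decision function) on the selected
#' panel.
#'
#' @inheritParams rfe
#' @return An `svm_rfe` object: `trace` (the [rfe()] trace), `panel` (the
#'   [select_optimal_panel()] result), `model` (final `svm_model` on the
#'   panel), `loocv` (LOOCV of the panel), `full_loocv` (LOOCV of the
#'   all-feature model, for comparison).
#' @examples
#' \donttest{
#' sim <- simulate_run_table(synthetic_config(n_case = 10, n_control = 10,
#'                                            n_features = 30,
#'                                            planted_panel_size = 4,
#'                                            n_batches = 2, seed = 2))
#' cur <- curate(sim$table, min_runs = 5)
#' fit <- svm_rfe(cur$matrix)
#' print(fit)
#' }
#' @export
svm_rfe <- function(x, y = NULL, cost = 1,
                    scaling_mode = c("global", "fold"), min_size = 1,
                    importance = c("signed_mean", "mean_abs"), tol = 1e-4,
                    verbose = FALSE) {
  scaling_mode <- match.arg(scaling_mode)
  importance <- match.arg(importance)
  d <- .as_xy(x, y)
  trace <- rfe(x, y, cost = cost, scaling_mode = scaling_mode,
               min_size = min_size, importance = importance, tol = tol,
               verbose = verbose)
  panel <- select_optimal_panel(trace)
  xp <- d$x[, panel$features, drop = FALSE]
  model <- train_linear_svm(xp, d$labels, cost = cost)
  loocv <- loocv_evaluate(xp, d$labels, cost = cost,
                          scaling_mode = scaling_mode, tol = tol)
  full_df <- summary(trace)[1, ]
  structure(list(trace = trace, panel = panel, model = model,
                 loocv = loocv,
                 full_loocv = c(accuracy = full_df$accuracy,
                                sensitivity = full_df$sensitivity,
                                specificity = full_df$specificity),
                 cost = cost, scaling_mode = scaling_mode),
            class = "svm_rfe")
}

#' @export
print.svm_rfe <- function(x, ...) {
  cat("Nested-LOOCV SVM-RFE panel selection\n")
  cat(sprintf("  all %d features: accuracy %.1f%% / sens %.1f%% / spec %.1f%%\n",
              x$trace$steps[[1]]$size, x$full_loocv["accuracy"],
              x$full_loocv["sensitivity"], x$full_loocv["specificity"]))
  print(x$panel)
  invisible(x)
}

#' @export
summary.svm_rfe <- function(object, ...) summary(object$trace)

#' @export
coef.svm_rfe <- function(object, ...) coef(object$model)

#' @export
predict.svm_rfe <- function(object, newdata, ...) {
  metabolic_score(object$model, newdata)
}

#' Panel-size versus accuracy curve from an RFE fit
#'
#' @param x an `svm_rfe` or `rfe_trace` object.
#' @param ... passed to [graphics::matplot()].
#' @return The plotted data frame, invisibly.
#' @export
plot.svm_rfe <- function(x, ...) {
  df <- summary(x$trace)
  graphics::matplot(df$size, df[, c("accuracy", "sensitivity", "specificity")],
                    type = "l", lty = 1:3, col = c(1, 2, 4),
                    xlab = "panel size", ylab = "LOOCV metric (%)",
                    main = "SVM-RFE panel size vs performance", ...)
  graphics::abline(v = x$panel$size, lty = 3, col = "grey40")
  graphics::legend("bottomright", c("accuracy", "sensitivity", "specificity"),
                   lty = 1:3, col = c(1, 2, 4), bty = "n")
  invisible(df)
}
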