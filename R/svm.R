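# Linear soft-margin SVM with the metabolic-score decision function.
# Class coding is fixed: N (control) -> -1, C (cancer) -> +1, so a
# positive score predicts cancer. The solver is an in-package SMO dual
# solver (linear kernel, unpenalized bias).

#' Class coding for the binary classifier
#'
#' Maps class labels to the numeric coding used throughout: control
#' `"N"` to -1 and cancer `"C"` to +1.
#'
#' @param labels character vector of `"C"`/`"N"` labels.
#' @return Numeric vector of -1/+1.
#' @export
class_coding <- function(labels) {
  if (!all(labels %in% c("C", "N")))
    stop("labels must be 'C' or 'N'")
  ifelse(labels == "C", 1, -1)
}

.as_xy <- function(x, y = NULL) {
  if (inherits(x, "sample_matrix")) {
    list(x = x$x, y = class_coding(x$samples$class_label),
         labels = x$samples$class_label, ids = x$samples$sample_id)
  } else {
    stopifnot(is.matrix(x), !is.null(y))
    labels <- if (is.numeric(y)) ifelse(y > 0, "C", "N") else y
    list(x = x, y = class_coding(labels), labels = labels,
         ids = rownames(x) %||% as.character(seq_len(nrow(x))))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Autoscale a feature matrix
#'
#' Centres each feature to mean 0 and scales to unit standard deviation
#' (sample SD, n - 1 denominator). The scaling parameters are returned so
#' held-out samples can be projected onto the same scale.
#'
#' @param x numeric matrix or [sample_matrix()].
#' @return For a matrix: list with `x` (scaled matrix), `center`, `scale`.
#'   For a `sample_matrix`: the same with `x` still a `sample_matrix`
#'   (negative entries allowed after scaling).
#' @export
autoscale <- function(x) {
  sm <- NULL
  if (inherits(x, "sample_matrix")) { sm <- x; x <- x$x }
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  zero <- scl == 0 | !is.finite(scl)
  if (any(zero))
    stop("zero-variance feature(s): ",
         paste(colnames(x)[zero] %||% which(zero), collapse = ", "))
  xs <- sweep(sweep(x, 2, ctr, "-"), 2, scl, "/")
  if (!is.null(sm)) {
    sm$x <- xs
    sm$autoscaled <- TRUE
    return(list(x = sm, center = ctr, scale = scl))
  }
  list(x = xs, center = ctr, scale = scl)
}

#' Train a linear soft-margin SVM
#'
#' Fits a linear C-SVC by sequential minimal optimization on the dual:
#' the separating hyperplane `w x' + b = 0` maximizes the margin between
#' classes subject to `c_i (w x_i' + b) >= 1 - xi_i` with slack penalty
#' `cost`. Only `w` is regularized; the bias is free. Features are
#' autoscaled before fitting unless a precomputed `scaling` is supplied,
#' and the scaling is stored in the model so raw-scale samples can be
#' scored.
#'
#' @param x a [sample_matrix()], or a numeric matrix with `y` given.
#' @param y class labels (`"C"`/`"N"` or +1/-1) when `x` is a bare matrix.
#' @param cost soft-margin regularization constant C (default 1).
#' @param scaling optional list with `center` and `scale` to use instead
#'   of autoscaling on `x`; pass `FALSE` to fit on `x` as-is (identity
#'   scaling).
#' @param tol SMO convergence tolerance on the duality gap.
#' @return An `svm_model` with elements `w` (named weight vector), `b`
#'   (bias), `feature_ids`, `scaling`, `cost`.
#' @examples
#' x <- matrix(c(-1, 1), 2, 1, dimnames = list(NULL, "f1"))
#' m <- train_linear_svm(x, c("N", "C"), cost = 1e3, scaling = FALSE)
#' c(w = unname(m$w), b = m$b) # max-margin solution w = 1, b = 0
#' @export
train_linear_svm <- function(x, y = NULL, cost = 1, scaling = NULL,
                             tol = 1e-6) {
  d <- .as_xy(x, y)
  if (length(unique(d$y)) < 2)
    stop("both classes must be present in the training data")
  if (ncol(d$x) < 1) stop("at least one feature is required")
  if (cost <= 0) stop("cost must be positive")
  if (isFALSE(scaling)) {
    scaling <- list(center = setNames(numeric(ncol(d$x)), colnames(d$x)),
                    scale = setNames(rep(1, ncol(d$x)), colnames(d$x)))
    xs <- d$x
  } else if (is.null(scaling)) {
    sc <- autoscale(d$x)
    xs <- sc$x
    scaling <- list(center = sc$center, scale = sc$scale)
  } else {
    xs <- sweep(sweep(d$x, 2, scaling$center, "-"), 2, scaling$scale, "/")
  }
  fit <- cpp_svm_train(xs, d$y, cost, tol)
  if (!fit$converged)
    warning("SMO did not converge within the iteration cap")
  structure(list(w = setNames(fit$w, colnames(d$x)), b = fit$b,
                 feature_ids = colnames(d$x), scaling = scaling,
                 cost = cost, n_support = sum(fit$alpha > 0)),
            class = "svm_model")
}

#' @export
print.svm_model <- function(x, ...) {
  cat(sprintf("Linear SVM model: %d features, cost = %g, %d support vectors\n",
              length(x$w), x$cost, x$n_support))
  cat(sprintf("  bias b = %.4g; largest |w|: %s\n", x$b,
              paste(names(sort(abs(x$w), decreasing = TRUE))[
                seq_len(min(5, length(x$w)))], collapse = ", ")))
  invisible(x)
}

#' @export
coef.svm_model <- function(object, ...) c(object$w, bias = object$b)

#' Metabolic score and predicted class
#'
#' The decision value `w x' + b` on the autoscaled sample vector: positive
#' scores predict cancer (C), negative scores control (N). A score of
#' exactly 0 is classified N (the conservative call for a screening
#' score) with a warning.
#'
#' @param model an `svm_model`.
#' @param x raw-scale sample vector, matrix or [sample_matrix()]; the
#'   model's stored scaling is applied internally.
#' @return `data.frame` with columns `score` and `class`.
#' @export
metabolic_score <- function(model, x) {
  stopifnot(inherits(model, "svm_model"))
  if (inherits(x, "sample_matrix")) x <- x$x
  if (!is.matrix(x)) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  if (!is.null(colnames(x))) {
    if (!all(model$feature_ids %in% colnames(x)))
      stop("sample is missing model feature(s): ",
           paste(setdiff(model$feature_ids, colnames(x)), collapse = ", "))
    x <- x[, model$feature_ids, drop = FALSE]
  } else if (ncol(x) != length(model$w)) {
    stop("sample has ", ncol(x), " features; model expects ",
         length(model$w))
  }
  xs <- sweep(sweep(x, 2, model$scaling$center, "-"), 2,
              model$scaling$scale, "/")
  score <- drop(xs %*% model$w) + model$b
  if (any(score == 0))
    warning("sample(s) on the separating hyperplane (score 0) classified N")
  data.frame(score = score,
             class = ifelse(score > 0, "C", "N"),
             row.names = rownames(x), stringsAsFactors = FALSE)
}

#' @export
predict.svm_model <- function(object, newdata, ...) {
  metabolic_score(object, newdata)
}

.classify_scores <- function(score) {
  if (any(score == 0))
    warning("held-out sample(s) on the separating hyperplane classified N")
  ifelse(score > 0, "C", "N")
}

.binary_metrics <- function(truth, predicted) {
  c(accuracy = 100 * mean(predicted == truth),
    sensitivity = 100 * mean(predicted[truth == "C"] == "C"),
    specificity = 100 * mean(predicted[truth == "N"] == "N"))
}

#' Leave-one-out cross-validated evaluation
#'
#' Trains n models each on n - 1 samples and scores the held-out sample.
#' Two scaling modes: `"global"` autoscales the full matrix once before
#' the folds (matches a workflow that autoscales prior to model building,
#' at the cost of mild information leakage into the folds), `"fold"`
#' recomputes the scaling from each training fold (strict).
#'
#' @param x a [sample_matrix()], or a matrix with `y`.
#' @param y class labels when `x` is a bare matrix.
#' @param cost SVM regularization constant.
#' @param scaling_mode `"global"` or `"fold"`.
#' @param tol SMO tolerance (a looser tolerance than single-model fits is
#'   the default; the decision sign is insensitive to it).
#' @return A `loocv_result`: `accuracy`, `sensitivity`, `specificity` (in
#'   percent), `scores` (held-out metabolic score per sample), `predicted`,
#'   `truth`, `avg_w` (per-feature weight averaged over the n fold models).
#' @export
loocv_evaluate <- function(x, y = NULL, cost = 1,
                           scaling_mode = c("global", "fold"), tol = 1e-4) {
  d <- .as_xy(x, y)
  scaling_mode <- match.arg(scaling_mode)
  n <- nrow(d$x)
  if (min(table(d$labels)) < 2)
    stop("each class needs at least 2 samples for LOOCV")
  if (scaling_mode == "global") {
    xs <- autoscale(d$x)$x
    res <- cpp_svm_loocv(xs, d$y, cost, tol)
    scores <- setNames(res$scores, d$ids)
    avg_w <- setNames(res$avg_w, colnames(d$x))
  } else {
    scores <- setNames(numeric(n), d$ids)
    avg_w <- setNames(numeric(ncol(d$x)), colnames(d$x))
    for (i in seq_len(n)) {
      m <- train_linear_svm(d$x[-i, , drop = FALSE], d$labels[-i],
                            cost = cost, tol = tol)
      scores[i] <- metabolic_score(m, d$x[i, , drop = FALSE])$score
      avg_w <- avg_w + m$w / n
    }
  }
  predicted <- .classify_scores(scores)
  metrics <- .binary_metrics(d$labels, predicted)
  structure(list(accuracy = metrics[["accuracy"]],
                 sensitivity = metrics[["sensitivity"]],
                 specificity = metrics[["specificity"]],
                 scores = scores, predicted = predicted, truth = d$labels,
                 avg_w = avg_w, cost = cost, scaling_mode = scaling_mode),
            class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf(
    "LOOCV (%s scaling): accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%\n",
    x$scaling_mode, x$accuracy, x$sensitivity, x$specificity))
  invisible(x)
}
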