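# Univariate per-feature summaries (signed fold change, Mann-Whitney U)
# and PCA-based experimental-bias inspection.

#' Signed fold change between class means
#'
#' Ratio of class-mean areas with the sign carrying direction: positive
#' when the cancer (C) mean is the larger, negative when the control (N)
#' mean is the larger; magnitude is always >= 1 (equal means give +1).
#'
#' @param mean_c,mean_n positive class-mean areas (vectorized).
#' @return Signed fold change.
#' @examples
#' signed_fold_change(2, 1) # +2
#' signed_fold_change(1, 2) # -2
#' @export
signed_fold_change <- function(mean_c, mean_n) {
  if (any(mean_c <= 0) || any(mean_n <= 0))
    stop("class means must be positive")
  ifelse(mean_c >= mean_n, mean_c / mean_n, -mean_n / mean_c)
}

#' Mann-Whitney U test between two groups
#'
#' Wraps the Wilcoxon rank-sum machinery: the exact two-sided p-value for
#' small untied samples, the normal approximation with tie correction
#' otherwise. The reported U is the smaller of the two one-sided U
#' statistics (`min(U_C, U_N)`).
#'
#' @param group_c,group_n numeric vectors of areas (both nonempty).
#' @param exact logical or `NULL` (automatic: exact when both groups have
#'   <= 8 observations and there are no ties).
#' @return List with `U`, `p_value`.
#' @examples
#' mann_whitney(c(4, 5, 6), c(1, 2, 3)) # U = 0, p = 0.1
#' @export
mann_whitney <- function(group_c, group_n, exact = NULL) {
  if (length(group_c) == 0 || length(group_n) == 0)
    stop("both groups must be nonempty")
  ties <- any(duplicated(c(group_c, group_n)))
  if (is.null(exact))
    exact <- length(group_c) <= 8 && length(group_n) <= 8 && !ties
  wt <- suppressWarnings(wilcox.test(group_c, group_n, exact = exact,
                                     correct = !exact))
  u_c <- unname(wt$statistic)
  u <- min(u_c, length(group_c) * length(group_n) - u_c)
  list(U = u, p_value = wt$p.value)
}

#' Per-feature univariate summaries
#'
#' For every feature: class-mean areas, signed fold change, Mann-Whitney U
#' and two-sided p, and a significance tier (`"p<0.05"`, `"p<0.10"`,
#' `"ns"`). Features whose class mean is zero get `NA` fold change (no
#' ratio is defined for an absent class mean).
#'
#' @param x a [sample_matrix()].
#' @param features optional subset of feature ids (default all).
#' @return `data.frame` with one row per feature: `feature_id`, `mean_C`,
#'   `mean_N`, `fold_change`, `U`, `p_value`, `tier`.
#' @export
feature_summaries <- function(x, features = NULL) {
  stopifnot(inherits(x, "sample_matrix"))
  if (is.null(features)) features <- colnames(x$x)
  cl <- x$samples$class_label
  out <- lapply(features, function(f) {
    v <- x$x[, f]
    mc <- mean(v[cl == "C"]); mn <- mean(v[cl == "N"])
    mw <- mann_whitney(v[cl == "C"], v[cl == "N"])
    fc <- if (mc > 0 && mn > 0) signed_fold_change(mc, mn) else NA_real_
    data.frame(feature_id = f, mean_C = mc, mean_N = mn, fold_change = fc,
               U = mw$U, p_value = mw$p_value,
               tier = if (mw$p_value < 0.05) "p<0.05"
                      else if (mw$p_value < 0.10) "p<0.10" else "ns",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' PCA inspection for experimental bias
#'
#' Autoscaled principal component analysis with a quantitative
#' batch-association summary: the ratio of between-group to within-group
#' mean squares of the PC1/PC2 scores (an F-like statistic; large values
#' flag clustering by the grouping label). The grouping label is typically
#' collection day, analysis batch or sample origin.
#'
#' @param x a [sample_matrix()] or numeric matrix.
#' @param labels grouping label per sample, or the name of a sample
#'   metadata column (`"batch_id"`, `"site_id"`) when `x` is a
#'   `sample_matrix`.
#' @return List with `scores` (PC1/PC2 per sample), `variance_explained`
#'   (proportions, all components), `association` (the F-like ratio),
#'   `labels`.
#' @export
pca_bias_check <- function(x, labels = "batch_id") {
  if (inherits(x, "sample_matrix")) {
    if (is.character(labels) && length(labels) == 1 &&
        labels %in% names(x$samples))
      labels <- x$samples[[labels]]
    x <- x$x
  }
  stopifnot(is.matrix(x))
  if (nrow(x) < 3) stop("need at least 3 samples for PCA")
  if (length(labels) != nrow(x))
    stop("labels length must match the number of samples")
  keep <- apply(x, 2, sd) > 0
  xs <- autoscale(x[, keep, drop = FALSE])$x
  pc <- prcomp(xs, center = FALSE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  s <- pc$x[, 1:2, drop = FALSE]
  g <- as.factor(labels)
  grand <- colMeans(s)
  between <- 0; within <- 0
  for (lev in levels(g)) {
    rows <- g == lev
    m <- colMeans(s[rows, , drop = FALSE])
    between <- between + sum(rows) * sum((m - grand)^2)
    within <- within + sum(sweep(s[rows, , drop = FALSE], 2, m)^2)
  }
  n <- nrow(s); G <- nlevels(g)
  assoc <- (between / max(G - 1, 1)) / (within / max(n - G, 1))
  list(scores = s, variance_explained = ve, association = assoc,
       labels = g)
}
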