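# Peak-list curation: presence filter, total-area normalization, pooled-QC
# drift purge, blank-baseline purge, duplicate averaging. Filters operate
# on a run_table and compose in that order inside curate().

#' Presence filter
#'
#' Removes features not detected (non-missing, area > 0) in at least
#' `min_runs` of the collected runs.
#'
#' @param x a [run_table()].
#' @param min_runs minimum number of runs a feature must be present in
#'   (default 40, the conservative threshold used on a 237-run study).
#' @param total_runs informational total (defaults to the table's run
#'   count); must be >= `min_runs`.
#' @return The filtered `run_table`, with removed feature ids in
#'   `attr(, "removed_features")`.
#' @export
presence_filter <- function(x, min_runs = 40, total_runs = nrow(x$areas)) {
  stopifnot(inherits(x, "run_table"))
  if (min_runs < 0) stop("min_runs must be non-negative")
  if (min_runs > total_runs)
    stop("min_runs (", min_runs, ") exceeds total runs (", total_runs, ")")
  present <- colSums(!is.na(x$areas) & x$areas > 0)
  keep <- present >= min_runs
  out <- .keep_features(x, keep)
  attr(out, "removed_features") <- colnames(x$areas)[!keep]
  out
}

#' Total-area (TIC) normalization
#'
#' Divides each run's peak areas by that run's total peak area, so every
#' run's areas sum to 1. Missing peaks stay missing and do not contribute
#' to the total.
#'
#' @param x a [run_table()].
#' @return The normalized `run_table`.
#' @export
tic_normalize <- function(x) {
  stopifnot(inherits(x, "run_table"))
  tot <- rowSums(x$areas, na.rm = TRUE)
  bad <- which(tot <= 0)
  if (length(bad))
    stop("run_index ", paste(x$meta$run_index[bad], collapse = ", "),
         " has zero total peak area")
  x$areas <- x$areas / tot
  x
}

#' Pooled-QC drift filter
#'
#' For each feature, regresses the pooled-QC peak area on acquisition
#' order (or acquisition time) by ordinary least squares and removes the
#' feature when the slope differs from zero by more than one standard
#' deviation. Two readings of "one standard deviation" are available:
#' \describe{
#'   \item{`"slope_se"` (default)}{|slope| > SE(slope), the standard error
#'     of the OLS slope estimator — the dimensionally coherent reading.}
#'   \item{`"span_sd"`}{|slope| x (x-range) > SD(QC areas): the drift over
#'     the acquisition span exceeds one SD of the QC areas.}
#' }
#' Missing QC peaks are treated as area 0 (not detected).
#'
#' @param x a [run_table()] containing at least 3 pooled-QC runs.
#' @param rule `"slope_se"` or `"span_sd"`.
#' @param time_axis `"run_index"` (acquisition order, default) or
#'   `"acquisition_time"`.
#' @return List with `table` (filtered `run_table`), `removed` (feature
#'   ids) and `slopes` (per-feature slope and SE).
#' @export
qc_drift_filter <- function(x, rule = c("slope_se", "span_sd"),
                            time_axis = c("run_index", "acquisition_time")) {
  stopifnot(inherits(x, "run_table"))
  rule <- match.arg(rule)
  time_axis <- match.arg(time_axis)
  qc <- x$meta$role == "qc_pool"
  m <- sum(qc)
  if (m < 3)
    stop("need at least 3 pooled-QC runs to estimate a drift slope (found ",
         m, ")")
  tt <- x$meta[[time_axis]][qc]
  a <- x$areas[qc, , drop = FALSE]
  a[is.na(a)] <- 0
  xc <- tt - mean(tt)
  sxx <- sum(xc^2)
  beta <- drop(crossprod(xc, a)) / sxx
  fitted <- outer(xc, beta) + rep(colMeans(a), each = m)
  rss <- colSums((a - fitted)^2)
  if (rule == "slope_se") {
    se <- sqrt(rss / (m - 2) / sxx)
    remove <- abs(beta) > se
  } else {
    sd_a <- apply(a, 2, sd)
    remove <- abs(beta) * diff(range(tt)) > sd_a
  }
  out <- .keep_features(x, !remove)
  list(table = out, removed = colnames(x$areas)[remove],
       slopes = data.frame(feature_id = colnames(x$areas),
                           slope = beta, se = if (rule == "slope_se") se else NA,
                           removed = remove, row.names = NULL))
}

#' Blank-baseline filter
#'
#' Purges features that do not rise above a multiple of the blank-run
#' baseline in at least a given share of any sample group (all study
#' samples, class C, or class N). The baseline is the maximum peak area
#' observed in the blank runs, computed per feature by default or as a
#' single global scalar.
#'
#' @param x a [run_table()] containing at least one blank run.
#' @param fraction required share of a group at/above the threshold
#'   (default 0.5).
#' @param multiple baseline multiple defining "present above baseline"
#'   (default 10).
#' @param per_feature if `TRUE` (default) the baseline is per feature; if
#'   `FALSE` one global scalar (max over all blanks and features) is used.
#' @return List with `table` (filtered `run_table`), `removed` (feature
#'   ids) and `baseline` (the per-feature vector or global scalar used).
#' @export
baseline_filter <- function(x, fraction = 0.5, multiple = 10,
                            per_feature = TRUE) {
  stopifnot(inherits(x, "run_table"))
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  if (multiple < 0) stop("multiple must be non-negative")
  blank <- x$meta$role == "blank"
  if (!any(blank)) stop("no blank runs present; baseline undefined")
  b <- x$areas[blank, , drop = FALSE]
  b[is.na(b)] <- 0
  baseline <- if (per_feature) apply(b, 2, max) else max(b)
  study <- x$meta$role == "study"
  a <- x$areas[study, , drop = FALSE]
  a[is.na(a)] <- 0
  cl <- x$meta$class_label[study]
  thr <- multiple * baseline  # per-feature vector or scalar, recycled
  share <- function(rows) colMeans(sweep(a[rows, , drop = FALSE], 2,
                                         rep(thr, length.out = ncol(a)),
                                         ">=") * 1)
  pass <- share(seq_len(nrow(a))) >= fraction
  for (g in c("C", "N"))
    if (any(cl == g)) pass <- pass | share(cl == g) >= fraction
  out <- .keep_features(x, pass)
  list(table = out, removed = colnames(x$areas)[!pass], baseline = baseline)
}

#' Average duplicate injections into a sample matrix
#'
#' Collapses the run table to one row per study sample by averaging the
#' replicate injections of each sample per feature. A peak missing in a
#' replicate contributes 0 to the mean (absent in both replicates averages
#' to 0); QC and blank runs are excluded.
#'
#' @param x a [run_table()].
#' @return A [sample_matrix()].
#' @export
average_duplicates <- function(x) {
  stopifnot(inherits(x, "run_table"))
  study <- x$meta$role == "study"
  if (!any(study)) stop("no study runs present")
  meta <- x$meta[study, , drop = FALSE]
  a <- x$areas[study, , drop = FALSE]
  a[is.na(a)] <- 0
  ids <- unique(meta$sample_id)
  xm <- matrix(0, length(ids), ncol(a),
               dimnames = list(ids, colnames(a)))
  for (i in seq_along(ids)) {
    rows <- meta$sample_id == ids[i]
    xm[i, ] <- colMeans(a[rows, , drop = FALSE])
  }
  first <- match(ids, meta$sample_id)
  samples <- data.frame(sample_id = ids,
                        class_label = meta$class_label[first],
                        batch_id = meta$batch_id[first],
                        site_id = meta$site_id[first],
                        age = meta$age[first],
                        stringsAsFactors = FALSE)
  sample_matrix(xm, samples)
}

#' Samples-by-features matrix with class labels
#'
#' The modelling substrate: duplicate-averaged, normalized peak areas with
#' one row per study sample.
#'
#' @param x numeric matrix (samples x features), non-negative, no missing
#'   entries; rownames are sample ids.
#' @param samples `data.frame` with columns `sample_id`, `class_label`
#'   (values `"C"`/`"N"`) and optionally `batch_id`, `site_id`, `age`.
#' @return A `sample_matrix` object.
#' @export
sample_matrix <- function(x, samples) {
  stopifnot(is.matrix(x), is.data.frame(samples),
            all(c("sample_id", "class_label") %in% names(samples)))
  if (nrow(x) != nrow(samples)) stop("matrix and sample metadata rows differ")
  if (anyNA(x)) stop("sample matrix must not contain missing entries")
  if (any(x < 0)) stop("sample matrix entries must be non-negative")
  if (any(duplicated(samples$sample_id))) stop("duplicated sample_id")
  if (!all(samples$class_label %in% c("C", "N")))
    stop("class_label must be 'C' or 'N'")
  rownames(x) <- samples$sample_id
  structure(list(x = x, samples = samples), class = "sample_matrix")
}

#' @export
print.sample_matrix <- function(x, ...) {
  cat(sprintf("Sample matrix: %d samples (C: %d, N: %d) x %d features\n",
              nrow(x$x), sum(x$samples$class_label == "C"),
              sum(x$samples$class_label == "N"), ncol(x$x)))
  invisible(x)
}

#' @export
dim.sample_matrix <- function(x) dim(x$x)

#' @export
feature_ids.sample_matrix <- function(x) colnames(x$x)

#' Subset a sample matrix to selected features
#' @param x a `sample_matrix`.
#' @param features character vector of feature ids (or column indices).
#' @return A `sample_matrix` restricted to `features`.
#' @export
select_features <- function(x, features) {
  stopifnot(inherits(x, "sample_matrix"))
  sample_matrix(x$x[, features, drop = FALSE], x$samples)
}

#' Full curation pipeline
#'
#' Applies, in order: presence filter, total-area normalization, pooled-QC
#' drift filter, blank-baseline filter, duplicate averaging. The report
#' records the features removed at each stage and the counts before/after.
#'
#' @param x a [run_table()].
#' @param min_runs presence threshold (default 40).
#' @param fraction,multiple,per_feature baseline-filter parameters.
#' @param qc_rule,time_axis QC drift-filter parameters.
#' @param normalize_first if `TRUE` (default) normalization precedes the
#'   QC and baseline filters, matching a workflow that normalizes exported
#'   areas before feature vetting; set `FALSE` to filter on raw areas.
#' @return List with `matrix` (a [sample_matrix()]) and `report`
#'   (a `curation_report`).
#' @export
curate <- function(x, min_runs = 40, fraction = 0.5, multiple = 10,
                   per_feature = TRUE, qc_rule = "slope_se",
                   time_axis = "run_index", normalize_first = TRUE) {
  stopifnot(inherits(x, "run_table"))
  n0 <- ncol(x$areas)
  stages <- list()

  cur <- presence_filter(x, min_runs = min_runs)
  stages$presence <- attr(cur, "removed_features")

  if (normalize_first) cur <- tic_normalize(cur)

  qd <- qc_drift_filter(cur, rule = qc_rule, time_axis = time_axis)
  cur <- qd$table
  stages$qc_drift <- qd$removed

  bf <- baseline_filter(cur, fraction = fraction, multiple = multiple,
                        per_feature = per_feature)
  cur <- bf$table
  stages$baseline <- bf$removed

  if (!normalize_first) cur <- tic_normalize(cur)

  if (ncol(cur$areas) == 0)
    stop("no features survive curation")
  sm <- average_duplicates(cur)

  counts <- c(input = n0,
              after_presence = n0 - length(stages$presence),
              after_qc_drift = n0 - length(stages$presence) -
                length(stages$qc_drift),
              after_baseline = ncol(cur$areas))
  report <- structure(list(removed = stages, counts = counts,
                           baseline = bf$baseline,
                           params = list(min_runs = min_runs,
                                         fraction = fraction,
                                         multiple = multiple,
                                         per_feature = per_feature,
                                         qc_rule = qc_rule,
                                         time_axis = time_axis,
                                         normalize_first = normalize_first)),
                      class = "curation_report")
  list(matrix = sm, report = report)
}

#' @export
print.curation_report <- function(x, ...) {
  cat("Curation report\n")
  cat(sprintf("  input features:        %d\n", x$counts["input"]))
  cat(sprintf("  presence filter:      -%d -> %d\n",
              length(x$removed$presence), x$counts["after_presence"]))
  cat(sprintf("  QC drift filter:      -%d -> %d\n",
              length(x$removed$qc_drift), x$counts["after_qc_drift"]))
  cat(sprintf("  baseline filter:      -%d -> %d\n",
              length(x$removed$baseline), x$counts["after_baseline"]))
  invisible(x)
}
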