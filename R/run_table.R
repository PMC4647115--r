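# Run-level peak-area table: acquisition metadata plus a runs x features
# area matrix. Absent peaks are NA; everything downstream treats absence
# as "not detected".

.META_COLS <- c("run_index", "sample_id", "replicate_index", "role",
                "class_label", "batch_id", "site_id", "age",
                "acquisition_time")

#' Construct a run-level peak-area table
#'
#' @param meta `data.frame` with one row per run and columns `run_index`
#'   (unique acquisition order), `sample_id`, `replicate_index`, `role`
#'   (`"study"`, `"qc_pool"` or `"blank"`), `class_label` (`"C"`, `"N"`, or
#'   `"none"` for non-study runs), `batch_id`, `site_id`, `age`,
#'   `acquisition_time`.
#' @param areas numeric matrix (runs x features) of non-negative peak
#'   areas, `NA` where a peak was not detected; column names are feature
#'   ids.
#' @return A `run_table` object.
#' @export
run_table <- function(meta, areas) {
  stopifnot(is.data.frame(meta), is.matrix(areas))
  areas <- `mode<-`(areas, "numeric")
  missing_cols <- setdiff(.META_COLS, names(meta))
  if (length(missing_cols))
    stop("metadata is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(meta) != nrow(areas))
    stop("metadata rows (", nrow(meta), ") and area rows (", nrow(areas),
         ") differ")
  if (is.null(colnames(areas))) stop("area matrix must have feature ids")
  x <- structure(list(meta = meta, areas = areas), class = "run_table")
  validate_run_table(x)
  x
}

#' Validate run-table invariants
#'
#' Checks unique run indexes, role/label consistency, replicate structure
#' and non-negative areas; errors name the offending run and feature.
#'
#' @param x a `run_table`.
#' @return `x`, invisibly, if valid.
#' @export
validate_run_table <- function(x) {
  meta <- x$meta; areas <- x$areas
  dup <- duplicated(meta$run_index)
  if (any(dup))
    stop("duplicated run_index: ", paste(unique(meta$run_index[dup]),
                                         collapse = ", "))
  bad_role <- !meta$role %in% c("study", "qc_pool", "blank")
  if (any(bad_role))
    stop("unknown role for run_index ",
         paste(meta$run_index[bad_role], collapse = ", "))
  study <- meta$role == "study"
  if (any(!meta$class_label[study] %in% c("C", "N")))
    stop("study runs must be labelled C or N")
  if (any(meta$class_label[!study] != "none"))
    stop("non-study runs must have class_label 'none'")
  neg <- which(areas < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop("negative peak area at run_index ",
         meta$run_index[neg[1, "row"]], ", feature ",
         colnames(areas)[neg[1, "col"]])
  }
  invisible(x)
}

#' @export
print.run_table <- function(x, ...) {
  tab <- table(x$meta$role)
  cat("Run-level peak-area table\n")
  cat(sprintf("  %d runs (%s), %d features\n", nrow(x$meta),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
              ncol(x$areas)))
  st <- x$meta$role == "study"
  cat(sprintf("  study samples: %d (C: %d, N: %d), batches: %d\n",
              length(unique(x$meta$sample_id[st])),
              length(unique(x$meta$sample_id[st & x$meta$class_label == "C"])),
              length(unique(x$meta$sample_id[st & x$meta$class_label == "N"])),
              length(unique(x$meta$batch_id[st]))))
  pct_na <- round(100 * mean(is.na(x$areas)), 1)
  cat(sprintf("  missing entries: %s%%\n", pct_na))
  invisible(x)
}

#' @export
dim.run_table <- function(x) dim(x$areas)

#' Feature ids of a run table
#' @param x a `run_table`.
#' @return Character vector of feature ids.
#' @export
feature_ids <- function(x) UseMethod("feature_ids")

#' @export
feature_ids.run_table <- function(x) colnames(x$areas)

# Subset features, preserving metadata.
.keep_features <- function(x, keep) {
  x$areas <- x$areas[, keep, drop = FALSE]
  x
}

#' Write a run table to CSV
#'
#' One row per run: the metadata columns followed by one column per
#' feature. Missing peaks are written as empty cells, so the round trip
#' through [read_run_table()] is lossless.
#'
#' @param x a `run_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_run_table <- function(x, path) {
  stopifnot(inherits(x, "run_table"))
  df <- cbind(x$meta[.META_COLS], as.data.frame(x$areas, optional = TRUE))
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a run table from CSV
#'
#' Inverse of [write_run_table()]. Malformed headers, duplicated run
#' indexes and negative areas are rejected with diagnostics naming the
#' offending row/feature.
#'
#' @param path CSV file path.
#' @return A `run_table`.
#' @export
read_run_table <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.META_COLS, names(df))
  if (length(missing_cols))
    stop("malformed header: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  feat <- setdiff(names(df), .META_COLS)
  if (length(feat) == 0) stop("malformed header: no feature columns")
  areas <- as.matrix(df[feat])
  mode(areas) <- "numeric"
  rownames(areas) <- NULL
  run_table(df[.META_COLS], areas)
}
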