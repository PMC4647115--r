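# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# Minimal run-table builder: meta defaults filled in from role/sample.
make_run_table <- function(areas, role, sample_id = NULL, class_label = NULL,
                           replicate_index = NULL, batch_id = 1,
                           site_id = "SITE1") {
  n <- nrow(areas)
  if (is.null(sample_id))
    sample_id <- ifelse(role == "study", paste0("S", seq_len(n)), role)
  if (is.null(class_label))
    class_label <- ifelse(role == "study", "C", "none")
  if (is.null(replicate_index))
    replicate_index <- ifelse(role == "study", 1L, NA_integer_)
  meta <- data.frame(
    run_index = seq_len(n), sample_id = sample_id,
    replicate_index = replicate_index, role = role,
    class_label = class_label, batch_id = batch_id, site_id = site_id,
    age = ifelse(role == "study", 60, NA_real_),
    acquisition_time = seq_len(n) * 0.5, stringsAsFactors = FALSE)
  run_table(meta, areas)
}

# Two-class sample matrix with planted mean shifts on the first `signal`
# features (gaussian, autoscale-friendly: strictly positive via offset).
make_class_matrix <- function(n_per_class = 10, p = 6, delta = 3,
                              signal = 2, seed = 1, sd = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- matrix(rnorm(n * p, mean = 50, sd = sd), n, p,
              dimnames = list(NULL, sprintf("f%02d", seq_len(p))))
  labels <- rep(c("C", "N"), each = n_per_class)
  if (signal > 0)
    x[labels == "C", seq_len(signal)] <- x[labels == "C", seq_len(signal)] + delta
  samples <- data.frame(sample_id = sprintf("S%02d", seq_len(n)),
                        class_label = labels, batch_id = 1, site_id = "SITE1",
                        age = 60, stringsAsFactors = FALSE)
  sample_matrix(x, samples)
}

# Curation fixture: 6 features, one engineered casualty per filter stage.
#   f1 -> presence filter (detected in only 5 of 14 runs, min_runs = 6)
#   f2 -> QC drift filter (strong linear trend across the QC injections)
#   f3 -> baseline filter (the only feature detected in blanks; its study
#         share never reaches 10x its blank share)
#   f4, f5, f6 -> survive all stages
# Layout: 8 study runs (4 samples x 2 replicates), 4 QC runs, 2 blanks.
# Survivor QC profiles use the symmetric (a, b, b, a) pattern: exactly
# zero OLS slope with nonzero residual, so the one-SE rule keeps them
# deterministically even after division by the (slightly trending) run
# totals.
make_curation_fixture <- function() {
  role <- c(rep("study", 8), rep("qc_pool", 4), rep("blank", 2))
  sample_id <- c(rep(c("S1", "S2", "S3", "S4"), 2), rep("qc_pool", 4),
                 rep("blank", 2))
  class_label <- c(rep(c("C", "C", "N", "N"), 2), rep("none", 6))
  replicate_index <- c(rep(1L, 4), rep(2L, 4), rep(NA_integer_, 6))
  # f2 is kept tiny in absolute area so its drift barely moves the run
  # totals; survivor QC patterns are mutually non-proportional so each
  # keeps its own residual after normalization.
  areas <- cbind(
    f1 = c(50, 50, 50, 50, 50, rep(NA, 9)),
    f2 = c(rep(0.2, 8), 0.1, 0.2, 0.3, 0.4, NA, NA),
    f3 = c(rep(30, 8), 30, 31.5, 31.5, 30, 5, 5),
    f4 = c(rep(100, 8), 100, 105, 105, 100, NA, NA),
    f5 = c(rep(200, 8), 210, 200, 200, 210, NA, NA),
    f6 = c(rep(10000, 8), 10000, 10300, 9700, 10000, NA, NA))
  make_run_table(areas, role, sample_id = sample_id,
                 class_label = class_label,
                 replicate_index = replicate_index)
}

# Orient an e1071 linear SVM so that class "C" is the positive side, and
# return its primal weight vector and bias.
e1071_linear <- function(x, labels, cost, tolerance = 1e-8) {
  fit <- e1071::svm(x, factor(labels), kernel = "linear", cost = cost,
                    scale = FALSE, tolerance = tolerance)
  w <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  d <- drop(x %*% w) + b
  if (mean(d[labels == "C"]) < mean(d[labels == "N"])) {
    w <- -w; b <- -b
  }
  list(w = w, b = b)
}
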