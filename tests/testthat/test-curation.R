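# Curation filters: boundary behavior, OLS drift oracle, baseline rule,
# duplicate averaging, composition and idempotence.

test_that("presence filter applies the at-least-min_runs boundary", {
  # 237 runs; feature A present in 39, feature B in 40, feature C in all
  n <- 237
  areas <- cbind(A = c(rep(1, 39), rep(NA, n - 39)),
                 B = c(rep(1, 40), rep(NA, n - 40)),
                 C = rep(1, n))
  rt <- make_run_table(areas, role = rep("study", n),
                       sample_id = paste0("S", seq_len(n)))
  out <- presence_filter(rt, min_runs = 40)
  expect_equal(colnames(out$areas), c("B", "C"))
  expect_equal(attr(out, "removed_features"), "A")
  # zero areas do not count as present
  areas2 <- cbind(A = c(rep(0, 200), rep(1, 37)), C = rep(1, n))
  rt2 <- make_run_table(areas2, role = rep("study", n),
                        sample_id = paste0("S", seq_len(n)))
  expect_equal(colnames(presence_filter(rt2, 40)$areas), "C")
  # degenerate threshold keeps everything
  expect_equal(ncol(presence_filter(rt, 0)$areas), 3)
  expect_error(presence_filter(rt, -1), "non-negative")
  expect_error(presence_filter(rt, 300), "exceeds")
})

test_that("TIC normalization yields unit row sums and scale invariance", {
  areas <- rbind(c(2, 3, 5), c(10, 30, 60))
  colnames(areas) <- c("a", "b", "c")
  rt <- make_run_table(areas, role = c("study", "study"),
                       sample_id = c("S1", "S2"))
  nt <- tic_normalize(rt)
  expect_equal(nt$areas[1, ], c(a = 0.2, b = 0.3, c = 0.5))
  expect_equal(unname(rowSums(nt$areas)), c(1, 1), tolerance = 1e-12)
  # scaling one run leaves its normalized row unchanged
  rt10 <- rt; rt10$areas[1, ] <- rt10$areas[1, ] * 10
  expect_equal(tic_normalize(rt10)$areas[1, ], nt$areas[1, ],
               tolerance = 1e-12)
  # idempotence
  expect_equal(tic_normalize(nt)$areas, nt$areas, tolerance = 1e-12)
  # zero-total runs are named
  rt0 <- rt; rt0$areas[2, ] <- c(0, 0, 0)
  expect_error(tic_normalize(rt0), "run_index 2")
})

test_that("QC drift filter matches a closed-form OLS oracle", {
  # 5 QC runs at indexes 8,16,...,40 plus surrounding study runs
  qc_y <- c(1.0, 1.1, 0.9, 1.05, 0.95)
  n <- 41
  role <- rep("study", n); role[c(8, 16, 24, 32, 40)] <- "qc_pool"
  # "stable" has exactly zero OLS slope but nonzero residual in QC
  areas <- cbind(stable = rep(1, n),
                 wobble = rep(2, n),
                 ramp = seq(1, 5, length.out = n))
  areas[role == "qc_pool", "stable"] <- c(1, 1.1, 1, 1.1, 1)
  areas[role == "qc_pool", "wobble"] <- qc_y
  rt <- make_run_table(areas, role,
                       sample_id = ifelse(role == "study",
                                          paste0("S", seq_len(n)), "qc_pool"),
                       class_label = ifelse(role == "study", "C", "none"))
  res <- qc_drift_filter(rt)

  # independent OLS on the QC subset decides each feature
  x <- c(8, 16, 24, 32, 40)
  oracle <- vapply(colnames(areas), function(f) {
    # suppressed: summary.lm warns on the zero-residual ramp fit
    fit <- suppressWarnings(summary(lm(areas[role == "qc_pool", f] ~ x)))
    co <- coef(fit)
    abs(co[2, 1]) > co[2, 2]
  }, TRUE)
  expect_equal(sort(res$removed), sort(names(oracle)[oracle]))
  # a zero-slope QC profile is kept
  expect_false("stable" %in% res$removed)
  # a strict linear trend with zero residual is removed
  expect_true("ramp" %in% res$removed)
  expect_error(qc_drift_filter(make_run_table(areas[1:3, , drop = FALSE],
                                              rep("study", 3))),
               "at least 3")
})

test_that("baseline filter keeps features above 10x baseline in any group", {
  # blank baseline 1 for every feature; 10 C and 10 N samples
  role <- c(rep("study", 20), "blank")
  cl <- c(rep("C", 10), rep("N", 10), "none")
  # highC: >= 10 in 60% of C only; low: 40% of each group; high: everywhere
  highC <- c(rep(10, 6), rep(1, 4), rep(1, 10), 1)
  low <- c(rep(10, 4), rep(1, 6), rep(10, 4), rep(1, 6), 1)
  high <- c(rep(50, 20), 1)
  rt <- make_run_table(cbind(highC = highC, low = low, high = high), role,
                       sample_id = c(paste0("S", 1:20), "blank"),
                       class_label = cl)
  res <- baseline_filter(rt, fraction = 0.5, multiple = 10)
  expect_equal(sort(colnames(res$table$areas)), c("high", "highC"))
  expect_equal(res$removed, "low")
  expect_equal(unname(res$baseline), c(1, 1, 1))
  # multiple = 0 keeps everything
  expect_equal(ncol(baseline_filter(rt, multiple = 0)$table$areas), 3)
  # global scalar baseline mode
  res_g <- baseline_filter(rt, per_feature = FALSE)
  expect_equal(res_g$baseline, 1)
  expect_error(baseline_filter(make_run_table(cbind(a = 1:3),
                                              rep("study", 3))),
               "no blank")
})

test_that("duplicate averaging treats missing as zero and drops QC/blanks", {
  role <- c("study", "study", "study", "study", "study", "qc_pool", "blank")
  sample_id <- c("S1", "S1", "S2", "S2", "S3", "qc_pool", "blank")
  cl <- c("C", "C", "N", "N", "C", "none", "none")
  areas <- cbind(f1 = c(2, 4, NA, 4, 4, 9, 9),
                 f2 = c(1, 1, 2, 2, NA, 9, 9))
  rt <- make_run_table(areas, role, sample_id = sample_id, class_label = cl,
                       replicate_index = c(1, 2, 1, 2, 1, NA, NA))
  sm <- average_duplicates(rt)
  expect_s3_class(sm, "sample_matrix")
  expect_equal(dim(sm$x), c(3, 2))
  expect_equal(unname(sm$x["S1", "f1"]), 3)   # (2 + 4) / 2
  expect_equal(unname(sm$x["S2", "f1"]), 2)   # (missing -> 0 + 4) / 2
  expect_equal(unname(sm$x["S3", "f1"]), 4)   # single replicate
  expect_equal(unname(sm$x["S3", "f2"]), 0)   # absent everywhere -> 0
  expect_equal(sm$samples$class_label, c("C", "N", "C"))
})

test_that("curation removes exactly the engineered casualty of each stage", {
  rt <- make_curation_fixture()
  out <- curate(rt, min_runs = 6)
  expect_equal(out$report$removed$presence, "f1")
  expect_equal(out$report$removed$qc_drift, "f2")
  expect_equal(out$report$removed$baseline, "f3")
  expect_equal(sort(feature_ids(out$matrix)), c("f4", "f5", "f6"))
  expect_equal(unname(out$report$counts),
               c(6, 5, 4, 3))
  expect_equal(nrow(out$matrix$x), 4)
  expect_true(all(out$matrix$x >= 0))

  # independent recheck of the drift decision on the normalized table
  nt <- tic_normalize(presence_filter(rt, 6))
  qc <- nt$meta$role == "qc_pool"
  xq <- nt$meta$run_index[qc]
  for (f in colnames(nt$areas)) {
    co <- coef(summary(lm(nt$areas[qc, f] ~ xq)))
    expect_equal(abs(co[2, 1]) > co[2, 2],
                 f %in% out$report$removed$qc_drift, info = f)
  }
})

test_that("curation on an all-clean table is the identity on features", {
  role <- c("qc_pool", rep("study", 4), "qc_pool", rep("study", 4),
            "qc_pool", "blank")
  sample_id <- ifelse(role == "study", paste0("S", c(1:4, 1:4))[
    pmax(cumsum(role == "study"), 1)], role)
  cl <- ifelse(role == "study",
               c("C", "C", "N", "N", "C", "C", "N", "N")[
                 pmax(cumsum(role == "study"), 1)], "none")
  # constant columns: QC slope exactly 0, blanks far below 10x rule
  areas <- matrix(rep(c(100, 200, 300, 150), each = 12), 12, 4,
                  dimnames = list(NULL, paste0("f", 1:4)))
  areas[role == "blank", ] <- 1e-6
  rt <- make_run_table(areas, role, sample_id = sample_id, class_label = cl)
  out <- curate(rt, min_runs = 3, normalize_first = FALSE)
  expect_equal(ncol(out$matrix$x), 4)
  expect_equal(unname(out$report$counts["input"]),
               unname(out$report$counts["after_baseline"]))
  expect_equal(lengths(out$report$removed), c(presence = 0L, qc_drift = 0L,
                                              baseline = 0L))
})

test_that("curation errors explicitly when nothing survives", {
  # every run (blanks included) has the same composition, so no feature
  # ever reaches 10x its blank share and the baseline purge removes all
  role <- c("qc_pool", rep("study", 4), "qc_pool", "qc_pool", "blank")
  areas <- matrix(rep(c(10, 12), each = 8), 8, 2,
                  dimnames = list(NULL, c("f1", "f2")))
  cl <- rep("none", 8); cl[role == "study"] <- c("C", "C", "N", "N")
  rt <- make_run_table(areas, role,
                       sample_id = ifelse(role == "study",
                                          paste0("S", seq_len(8)), role),
                       class_label = cl)
  expect_error(curate(rt, min_runs = 1), "no features survive")
})

test_that("each filter is idempotent on the default synthetic table", {
  sim <- simulate_run_table(synthetic_config(n_case = 10, n_control = 10,
                                             n_features = 40,
                                             planted_panel_size = 4,
                                             seed = 6))
  rt <- tic_normalize(sim$table)
  p1 <- presence_filter(rt, 10)
  expect_equal(presence_filter(p1, 10)$areas, p1$areas)
  q1 <- qc_drift_filter(p1)
  q2 <- qc_drift_filter(q1$table)
  expect_equal(q2$removed, character(0))
  expect_equal(q2$table$areas, q1$table$areas)
  b1 <- baseline_filter(q1$table)
  b2 <- baseline_filter(b1$table)
  expect_equal(b2$removed, character(0))
  expect_equal(b2$table$areas, b1$table$areas)
})

test_that("drift filter catches strong planted drift and spares at the t-rate", {
  # Drifting features here carry total drift >> noise over the run span.
  removed_drift <- removed_null <- numeric(0)
  for (s in 1:60) {
    cfg <- synthetic_config(n_case = 8, n_control = 8, n_features = 24,
                            planted_panel_size = 2,
                            drift_feature_fraction = 0.25,
                            drift_slope = 0.05, missing_rate = 0, seed = s)
    sim <- simulate_run_table(cfg)
    res <- qc_drift_filter(sim$table)  # raw areas: drift must not couple
                                       # features through normalization here
    drifters <- sim$truth$drift_feature_ids
    nulls <- setdiff(colnames(sim$table$areas), drifters)
    removed_drift <- c(removed_drift, mean(drifters %in% res$removed))
    removed_null <- c(removed_null, mean(nulls %in% res$removed))
  }
  # all strong drifters removed in at least 95% of seeds
  expect_gte(mean(removed_drift == 1), 0.95)
  # the |slope| > SE rule removes drift-free features at roughly the
  # t-distribution rate (~1/3) -- an intrinsic property of the threshold
  expect_gt(mean(removed_null), 0.15)
  expect_lt(mean(removed_null), 0.60)
})
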