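# Synthetic run-table generator emulating a duplicate-injection serum
# profiling study: lognormal peak areas, per-injection total-intensity
# scaling, batch structure, pooled-QC injections at fixed intervals,
# blanks, acquisition-order drift on a subset of features, detection-limit
# missingness, and a planted discriminative feature panel.

#' Configuration for the synthetic study generator
#'
#' Defaults emulate a two-class serum profiling design: 46 cancer (C) and
#' 49 control (N) sera run in duplicate across 8 batches with a pooled QC
#' injection every 8 study runs and blank runs, 255 features of which 16
#' planted discriminative features carry standardized log-scale effects
#' drawn from U(1.5, 2.5) with mixed signs.
#'
#' @param n_case,n_control study sample counts per class.
#' @param n_features total feature count.
#' @param planted_panel_size number of planted discriminative features.
#' @param effect_sizes optional vector (length `planted_panel_size`) of
#'   signed standardized log-scale mean shifts; by default magnitudes are
#'   drawn from U(1.5, 2.5) with random signs.
#' @param log_area_mu centre of per-feature base log-areas (natural log).
#' @param log_area_mu_sd spread of per-feature base log-areas.
#' @param log_area_sigma biological between-sample SD on the log scale;
#'   planted class shifts are `effect * log_area_sigma`.
#' @param replicate_cv fractional technical variation between duplicate
#'   injections of one sample.
#' @param tic_scale_sigma log-scale SD of the per-injection total-intensity
#'   multiplier.
#' @param qc_interval study runs between pooled-QC injections.
#' @param n_batches number of acquisition batches (class-balanced).
#' @param n_sites number of collection sites (assigned round-robin).
#' @param batch_effect_sigma log-scale SD of per-(batch, feature)
#'   multiplicative shifts.
#' @param drift_feature_fraction fraction of (non-planted) features given a
#'   monotone acquisition-order drift.
#' @param drift_slope per-run log-scale drift rate on drift features.
#' @param blank_baseline blank-run area level as a fraction of the
#'   per-feature median study area.
#' @param blank_detect_rate fraction of features that appear in blank runs
#'   as background/solvent signal (all other features are absent in
#'   blanks: a blank contains no serum metabolites).
#' @param n_blanks number of blank runs (one sample blank plus mobile-phase
#'   blanks).
#' @param missing_rate overall probability that a peak goes undetected;
#'   applied preferentially to low-abundance peaks (logistic in log-area),
#'   emulating detection-limit censoring.
#' @param seed RNG seed; identical seeds give bit-identical tables.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_case = 46, n_control = 49, n_features = 255,
                             planted_panel_size = 16, effect_sizes = NULL,
                             log_area_mu = 10, log_area_mu_sd = 1.5,
                             log_area_sigma = 0.5, replicate_cv = 0.12,
                             tic_scale_sigma = 0.2, qc_interval = 8,
                             n_batches = 8, n_sites = 4,
                             batch_effect_sigma = 0.1,
                             drift_feature_fraction = 0.05,
                             drift_slope = 0.004, blank_baseline = 0.01,
                             blank_detect_rate = 0.08, n_blanks = 11,
                             missing_rate = 0.05, seed = 1) {
  cfg <- list(n_case = n_case, n_control = n_control, n_features = n_features,
              planted_panel_size = planted_panel_size,
              effect_sizes = effect_sizes, log_area_mu = log_area_mu,
              log_area_mu_sd = log_area_mu_sd, log_area_sigma = log_area_sigma,
              replicate_cv = replicate_cv, tic_scale_sigma = tic_scale_sigma,
              qc_interval = qc_interval, n_batches = n_batches,
              n_sites = n_sites, batch_effect_sigma = batch_effect_sigma,
              drift_feature_fraction = drift_feature_fraction,
              drift_slope = drift_slope, blank_baseline = blank_baseline,
              blank_detect_rate = blank_detect_rate, n_blanks = n_blanks,
              missing_rate = missing_rate, seed = seed)
  counts <- c("n_case", "n_control", "n_features", "planted_panel_size",
              "n_batches", "n_sites")
  for (nm in counts)
    if (cfg[[nm]] < 1 || cfg[[nm]] != round(cfg[[nm]]))
      stop(nm, " must be a positive integer")
  if (cfg$planted_panel_size > cfg$n_features)
    stop("planted_panel_size exceeds n_features")
  if (cfg$qc_interval < 1) stop("qc_interval must be >= 1")
  if ((cfg$n_case + cfg$n_control) < 2 * cfg$n_batches)
    stop("each batch needs at least 2 samples (non-adjacent duplicate ",
         "injections are impossible otherwise); reduce n_batches")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (cfg$n_blanks < 1) stop("n_blanks must be >= 1")
  if (!is.null(effect_sizes) && length(effect_sizes) != planted_panel_size)
    stop("effect_sizes must have length planted_panel_size")
  structure(cfg, class = "synthetic_config")
}

# Shuffle run slots so that the two injections of a sample are never
# adjacent (run-order policy for duplicate injections).
.nonadjacent_order <- function(ids) {
  if (length(unique(ids)) < 2) return(ids)
  for (i in 1:200) {
    ord <- sample(ids)
    if (!any(ord[-1] == ord[-length(ord)])) return(ord)
  }
  # deterministic repair: swap an adjacent duplicate with a safe position
  for (k in 1:200) {
    adj <- which(ord[-1] == ord[-length(ord)])
    if (length(adj) == 0) break
    i <- adj[1] + 1
    ok <- which(ord != ord[i])
    j <- ok[sample.int(length(ok), 1)]
    tmp <- ord[i]; ord[i] <- ord[j]; ord[j] <- tmp
  }
  ord
}

#' Simulate a run-level peak-area table with planted ground truth
#'
#' Generates the acquisition sequence (class-balanced batches, duplicate
#' injections interleaved so replicates are never consecutive, a pooled QC
#' injection before every `qc_interval`-th study run, blanks spread across
#' the sequence) and lognormal peak areas with per-injection
#' total-intensity factors, per-(batch, feature) effects, acquisition
#' drift on a subset of features and detection-limit missingness. The
#' pooled QC composition is the average of all study-sample compositions,
#' mirroring physical pooling.
#'
#' @param config a [synthetic_config()].
#' @return List with elements `table` (a [run_table()]) and `truth`
#'   (ground truth: planted feature ids, signed effects, drift feature ids
#'   and per-sample class labels).
#' @examples
#' sim <- simulate_run_table(synthetic_config(n_case = 5, n_control = 5,
#'                                            n_features = 20,
#'                                            planted_panel_size = 4,
#'                                            n_batches = 2))
#' sim$table
#' @export
simulate_run_table <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(config$seed)
  cfg <- config

  n_samp <- cfg$n_case + cfg$n_control
  feat_ids <- sprintf("F%0*d", max(3, nchar(cfg$n_features)), seq_len(cfg$n_features))
  samp_ids <- c(sprintf("CASE%02d", seq_len(cfg$n_case)),
                sprintf("CTRL%02d", seq_len(cfg$n_control)))
  cls <- c(rep("C", cfg$n_case), rep("N", cfg$n_control))
  site <- paste0("SITE", 1 + (seq_len(n_samp) - 1) %% cfg$n_sites)
  age <- round(pmin(90, pmax(35, rnorm(n_samp, 60, 9))))

  # class-balanced batches: alternate C/N down the list, cut into chunks
  idxC <- which(cls == "C"); idxN <- which(cls == "N")
  k <- max(length(idxC), length(idxN))
  inter <- c(rbind(c(idxC, rep(NA, k - length(idxC))),
                   c(idxN, rep(NA, k - length(idxN)))))
  inter <- inter[!is.na(inter)]
  batch_of <- integer(n_samp)
  sizes <- diff(round(seq(0, n_samp, length.out = cfg$n_batches + 1)))
  batch_of[inter] <- rep(seq_len(cfg$n_batches), times = sizes)

  # feature-level parameters
  mu <- rnorm(cfg$n_features, cfg$log_area_mu, cfg$log_area_mu_sd)
  abundant <- which(mu >= median(mu))
  planted <- sort(sample(abundant, cfg$planted_panel_size))
  effects <- cfg$effect_sizes
  if (is.null(effects))
    effects <- runif(cfg$planted_panel_size, 1.5, 2.5) *
      sample(c(-1, 1), cfg$planted_panel_size, replace = TRUE)
  n_drift <- floor(cfg$drift_feature_fraction * cfg$n_features)
  drift_pool <- setdiff(seq_len(cfg$n_features), planted)
  drift <- sort(sample(drift_pool, min(n_drift, length(drift_pool))))
  # background/solvent features: the only ones a blank run detects
  n_bg <- round(cfg$blank_detect_rate * cfg$n_features)
  bg <- sort(sample(drift_pool, min(n_bg, length(drift_pool))))
  batch_fx <- matrix(rnorm(cfg$n_batches * cfg$n_features, 0,
                           cfg$batch_effect_sigma),
                     cfg$n_batches, cfg$n_features)

  # biological (per-sample) log composition
  shift <- matrix(0, n_samp, cfg$n_features)
  shift[cls == "C", planted] <- rep(effects * cfg$log_area_sigma / 2,
                                    each = cfg$n_case)
  shift[cls == "N", planted] <- rep(-effects * cfg$log_area_sigma / 2,
                                    each = cfg$n_control)
  bio <- matrix(rnorm(n_samp * cfg$n_features, 0, cfg$log_area_sigma),
                n_samp, cfg$n_features)
  log_comp <- sweep(bio + shift, 2, mu, "+")
  # pooled QC = average composition of all study samples (area scale)
  qc_log <- log(colMeans(exp(log_comp)))

  # acquisition sequence: per batch, shuffle duplicated samples with
  # non-adjacent replicates, then splice in QC and blank runs
  study_seq <- integer(0)
  for (b in seq_len(cfg$n_batches)) {
    members <- which(batch_of == b)
    if (length(members) == 0) next
    study_seq <- c(study_seq, .nonadjacent_order(rep(members, 2)))
  }
  n_study_runs <- length(study_seq)
  qc_after <- seq(0, n_study_runs, by = cfg$qc_interval)
  blank_after <- round(seq(0, n_study_runs, length.out = cfg$n_blanks))

  role <- c(rep("qc_pool", sum(qc_after == 0)),
            rep("blank", sum(blank_after == 0)))
  samp_seq <- rep(NA_integer_, length(role))
  for (i in seq_len(n_study_runs)) {
    role <- c(role, "study")
    samp_seq <- c(samp_seq, study_seq[i])
    n_qc <- sum(qc_after == i)
    n_bl <- sum(blank_after == i)
    if (n_qc + n_bl > 0) {
      role <- c(role, rep("qc_pool", n_qc), rep("blank", n_bl))
      samp_seq <- c(samp_seq, rep(NA_integer_, n_qc + n_bl))
    }
  }
  n_runs <- length(role)
  run_index <- seq_len(n_runs)

  # replicate index within sample, batch of each run
  rep_idx <- rep(NA_integer_, n_runs)
  seen <- integer(n_samp)
  batch_run <- rep(NA_integer_, n_runs)
  for (i in seq_len(n_runs)) {
    if (role[i] == "study") {
      s <- samp_seq[i]
      seen[s] <- seen[s] + 1L
      rep_idx[i] <- seen[s]
      batch_run[i] <- batch_of[s]
    }
  }
  # QC/blank runs inherit the batch of the nearest following study run
  last_b <- cfg$n_batches
  for (i in rev(seq_len(n_runs))) {
    if (is.na(batch_run[i])) batch_run[i] <- last_b else last_b <- batch_run[i]
  }

  tau <- sqrt(log(1 + cfg$replicate_cv^2))
  tic <- exp(rnorm(n_runs, 0, cfg$tic_scale_sigma))
  areas <- matrix(NA_real_, n_runs, cfg$n_features,
                  dimnames = list(NULL, feat_ids))
  drift_term <- function(i) {
    d <- numeric(cfg$n_features)
    d[drift] <- cfg$drift_slope * run_index[i]
    d
  }
  med_area <- exp(mu)  # blank reference level
  for (i in seq_len(n_runs)) {
    if (role[i] == "study") {
      base <- log_comp[samp_seq[i], ]
    } else if (role[i] == "qc_pool") {
      base <- qc_log
    } else {
      base <- log(cfg$blank_baseline * med_area)
    }
    noise_sd <- if (role[i] == "blank") 0.3 else tau
    row <- exp(base + rnorm(cfg$n_features, 0, noise_sd) +
                 batch_fx[batch_run[i], ] + drift_term(i)) * tic[i]
    if (role[i] == "blank") row[-bg] <- NA_real_
    areas[i, ] <- row
  }

  # detection-limit censoring on study + QC runs
  if (cfg$missing_rate > 0) {
    sq <- role != "blank"
    la <- log(areas[sq, , drop = FALSE])
    thr <- quantile(la, cfg$missing_rate)
    p_miss <- plogis((thr - la) / 0.4)
    miss <- matrix(runif(length(la)) < p_miss, nrow(la), ncol(la))
    areas[sq, ][miss] <- NA_real_
  }

  meta <- data.frame(
    run_index = run_index,
    sample_id = ifelse(is.na(samp_seq), role, samp_ids[samp_seq]),
    replicate_index = rep_idx,
    role = role,
    class_label = ifelse(role == "study", cls[ifelse(is.na(samp_seq), 1, samp_seq)],
                         "none"),
    batch_id = batch_run,
    site_id = ifelse(is.na(samp_seq), "none", site[ifelse(is.na(samp_seq), 1, samp_seq)]),
    age = ifelse(is.na(samp_seq), NA_real_, age[ifelse(is.na(samp_seq), 1, samp_seq)]),
    acquisition_time = round(run_index * 34 / 60, 3),
    stringsAsFactors = FALSE
  )

  truth <- list(
    planted_feature_ids = feat_ids[planted],
    effects = setNames(effects, feat_ids[planted]),
    drift_feature_ids = feat_ids[drift],
    background_feature_ids = feat_ids[bg],
    class_labels = setNames(cls, samp_ids)
  )
  list(table = run_table(meta, areas), truth = truth)
}

#' Write generator ground truth as a JSON sidecar
#'
#' @param truth the `truth` element of [simulate_run_table()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
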