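# Orthogonal PLS discriminant analysis (single predictive component,
# binary -1/+1 class code): orthogonal-signal-corrected PLS in the
# Trygg-Wold style. The predictive weight is w = X'y/||X'y||; each
# orthogonal component removes from X variation orthogonal to w, so the
# orthogonal scores carry no class covariance by construction.

.opls_core <- function(X, y0, n_ortho) {
  w <- drop(crossprod(X, y0))
  nw <- sqrt(sum(w^2))
  if (nw == 0) stop("response carries no covariance with any feature")
  w <- w / nw
  Wo <- Po <- matrix(0, ncol(X), 0)
  To <- matrix(0, nrow(X), 0)
  Xd <- X
  for (o in seq_len(n_ortho)) {
    t1 <- drop(Xd %*% w)
    p1 <- drop(crossprod(Xd, t1)) / sum(t1^2)
    wo <- p1 - sum(w * p1) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12)
      stop("no orthogonal variation left after ", o - 1, " component(s)")
    wo <- wo / nwo
    to <- drop(Xd %*% wo)
    po <- drop(crossprod(Xd, to)) / sum(to^2)
    Xd <- Xd - tcrossprod(to, po)
    Wo <- cbind(Wo, wo); Po <- cbind(Po, po); To <- cbind(To, to)
  }
  t_pred <- drop(Xd %*% w)
  p_pred <- drop(crossprod(Xd, t_pred)) / sum(t_pred^2)
  q <- sum(y0 * t_pred) / sum(t_pred^2)
  list(w = w, p = p_pred, q = q, t = t_pred, Wo = Wo, Po = Po, To = To)
}

#' Fit an orthogonal PLS-DA model
#'
#' Autoscales the feature matrix, codes the class as -1 (N) / +1 (C), and
#' fits one predictive component plus `n_ortho` orthogonal (class-
#' uncorrelated) components. With `n_ortho = 0` the model reduces to
#' one-component PLS-DA. When `n_ortho` is `NULL` it is chosen by
#' maximizing leave-one-out Q-squared over 0..3 components.
#'
#' @param x a [sample_matrix()], or a matrix with `y`.
#' @param y class labels when `x` is a bare matrix.
#' @param n_ortho number of orthogonal components (>= 0), or `NULL` to
#'   select by LOO Q-squared.
#' @return An `opls_model` with predictive weights/loadings/scores `w`,
#'   `p`, `q`, `scores`, orthogonal blocks `Wo`, `Po`, `To`, fitted `R2Y`,
#'   the scaling, and `n_ortho`.
#' @export
fit_oplsda <- function(x, y = NULL, n_ortho = NULL) {
  d <- .as_xy(x, y)
  if (length(unique(d$y)) < 2) stop("both classes must be present")
  if (is.null(n_ortho)) {
    q2 <- vapply(0:3, function(k) {
      if (k >= qr(d$x)$rank) return(-Inf)
      tryCatch(oplsda_cv(x, y, scheme = cv_scheme("loo"), n_ortho = k),
               error = function(e) -Inf)
    }, 0)
    n_ortho <- which.max(q2) - 1L
  }
  if (n_ortho < 0 || n_ortho != round(n_ortho))
    stop("n_ortho must be a non-negative integer")
  sc <- autoscale(d$x)
  Xs <- sc$x
  if (n_ortho >= qr(Xs)$rank)
    stop("n_ortho (", n_ortho, ") must be below the matrix rank (",
         qr(Xs)$rank, ")")
  ybar <- mean(d$y)
  core <- .opls_core(Xs, d$y - ybar, n_ortho)
  fitted <- core$t * core$q + ybar
  r2y <- 1 - sum((d$y - fitted)^2) / sum((d$y - mean(d$y))^2)
  structure(list(w = setNames(core$w, colnames(d$x)), p = core$p,
                 q = core$q, scores = setNames(core$t, d$ids),
                 Wo = core$Wo, Po = core$Po, To = core$To,
                 R2Y = r2y, n_ortho = n_ortho,
                 scaling = list(center = sc$center, scale = sc$scale),
                 y_mean = ybar, truth = d$labels, fitted = fitted),
            class = "opls_model")
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf(
    "oPLS-DA model: 1 predictive + %d orthogonal component(s), R2Y = %.3f\n",
    x$n_ortho, x$R2Y))
  invisible(x)
}

#' @export
predict.opls_model <- function(object, newdata, ...) {
  if (inherits(newdata, "sample_matrix")) newdata <- newdata$x
  if (!is.matrix(newdata))
    newdata <- matrix(newdata, nrow = 1, dimnames = list(NULL, names(newdata)))
  if (!is.null(colnames(newdata)))
    newdata <- newdata[, names(object$w), drop = FALSE]
  Xs <- sweep(sweep(newdata, 2, object$scaling$center, "-"), 2,
              object$scaling$scale, "/")
  for (o in seq_len(ncol(object$Wo))) {
    to <- drop(Xs %*% object$Wo[, o])
    Xs <- Xs - tcrossprod(to, object$Po[, o])
  }
  t_pred <- drop(Xs %*% object$w)
  yhat <- t_pred * object$q + object$y_mean
  data.frame(score = t_pred, y_pred = yhat,
             class = ifelse(yhat > 0, "C", "N"),
             row.names = rownames(newdata), stringsAsFactors = FALSE)
}

#' @export
residuals.opls_model <- function(object, ...) {
  class_coding(object$truth) - object$fitted
}

#' Cross-validation scheme specification
#'
#' @param kind `"loo"`, `"venetian_blinds"`, `"contiguous_blocks"` or
#'   `"random_subsets"`.
#' @param n_splits number of data splits (ignored for `"loo"`); defaults:
#'   venetian blinds 10 splits, contiguous blocks 10 splits, random
#'   subsets 10 splits.
#' @param n_iterations repeated random partitions for `"random_subsets"`
#'   (default 10).
#' @param seed seed for the random-subsets shuffles.
#' @return A `cv_scheme` object.
#' @export
cv_scheme <- function(kind = c("loo", "venetian_blinds",
                               "contiguous_blocks", "random_subsets"),
                      n_splits = 10, n_iterations = 10, seed = 1) {
  kind <- match.arg(kind)
  if (kind != "loo" && n_splits < 2) stop("n_splits must be >= 2")
  if (kind == "random_subsets" && n_iterations < 1)
    stop("n_iterations must be >= 1")
  structure(list(kind = kind, n_splits = n_splits,
                 n_iterations = n_iterations, seed = seed),
            class = "cv_scheme")
}

# fold assignment vector(s) for n samples under a scheme
.cv_folds <- function(scheme, n) {
  if (scheme$kind != "loo" && scheme$n_splits > n)
    stop("more splits (", scheme$n_splits, ") than samples (", n, ")")
  switch(scheme$kind,
    loo = list(seq_len(n)),
    venetian_blinds = list(((seq_len(n) - 1) %% scheme$n_splits) + 1),
    contiguous_blocks = list(rep(seq_len(scheme$n_splits),
                                 each = ceiling(n / scheme$n_splits))[seq_len(n)]),
    random_subsets = {
      if (exists(".Random.seed", globalenv())) {
        old_seed <- get(".Random.seed", globalenv())
        on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
      }
      set.seed(scheme$seed)
      lapply(seq_len(scheme$n_iterations), function(i)
        sample(rep(seq_len(scheme$n_splits), length.out = n)))
    })
}

#' Cross-validated Q-squared of an oPLS-DA model
#'
#' `Q2 = 1 - PRESS/TSS` over held-out class codes: each fold's model is
#' refit (including autoscaling) on the training samples only. Venetian
#' blinds assigns samples to splits cyclically by row index, contiguous
#' blocks by index ranges, random subsets averages over seeded repeated
#' random partitions.
#'
#' @param x a [sample_matrix()], or a matrix with `y`.
#' @param y class labels when `x` is a bare matrix.
#' @param scheme a [cv_scheme()].
#' @param n_ortho orthogonal component count (default 0).
#' @return Q-squared (scalar; averaged over iterations for random
#'   subsets).
#' @export
oplsda_cv <- function(x, y = NULL, scheme = cv_scheme("loo"), n_ortho = 0) {
  d <- .as_xy(x, y)
  stopifnot(inherits(scheme, "cv_scheme"))
  n <- nrow(d$x)
  folds_list <- .cv_folds(scheme, n)
  tss <- sum((d$y - mean(d$y))^2)
  q2s <- vapply(folds_list, function(folds) {
    press <- 0
    for (k in unique(folds)) {
      hold <- folds == k
      fit <- fit_oplsda(d$x[!hold, , drop = FALSE], d$labels[!hold],
                        n_ortho = n_ortho)
      pred <- predict(fit, d$x[hold, , drop = FALSE])$y_pred
      press <- press + sum((d$y[hold] - pred)^2)
    }
    1 - press / tss
  }, 0)
  mean(q2s)
}

#' Label-permutation test of oPLS-DA predictive ability
#'
#' Randomizes the class labels `n_perm` times, recomputes the
#' cross-validated Q-squared for each permutation, and reports the
#' add-one empirical p-value
#' `p = (1 + #\{permuted Q2 >= observed\}) / (n_perm + 1)`.
#'
#' @param x a [sample_matrix()], or a matrix with `y`.
#' @param y class labels when `x` is a bare matrix.
#' @param scheme a [cv_scheme()].
#' @param n_ortho orthogonal component count.
#' @param n_perm number of label permutations (>= 1).
#' @param seed RNG seed for the permutations.
#' @return List with `observed` Q2, `permuted` (vector of permuted Q2),
#'   `p_value`.
#' @export
permutation_test <- function(x, y = NULL, scheme = cv_scheme("loo"),
                             n_ortho = 0, n_perm = 99, seed = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  d <- .as_xy(x, y)
  observed <- oplsda_cv(d$x, d$labels, scheme = scheme, n_ortho = n_ortho)
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(seed)
  permuted <- vapply(seq_len(n_perm), function(i) {
    yp <- sample(d$labels)
    tryCatch(oplsda_cv(d$x, yp, scheme = scheme, n_ortho = n_ortho),
             error = function(e) -Inf)
  }, 0)
  p <- (1 + sum(permuted >= observed)) / (n_perm + 1)
  list(observed = observed, permuted = permuted, p_value = p)
}

#' Validate a feature panel by oPLS-DA under several CV schemes
#'
#' Convenience wrapper reporting fitted R2Y, Q-squared under
#' leave-one-out, venetian-blinds, contiguous-block and random-subset
#' cross-validation, and a label-permutation p-value.
#'
#' @param x a [sample_matrix()], or a matrix with `y`.
#' @param y class labels when `x` is a bare matrix.
#' @param n_ortho orthogonal components (`NULL`: LOO-Q2 selection, cap 3).
#' @param n_perm permutations for the test (default 99).
#' @param seed RNG seed for random subsets and permutations.
#' @return List with `R2Y`, `n_ortho`, `Q2` (named per scheme),
#'   `permutation` (from [permutation_test()], LOO scheme).
#' @export
oplsda_validate <- function(x, y = NULL, n_ortho = NULL, n_perm = 99,
                            seed = 1) {
  d <- .as_xy(x, y)
  fit <- fit_oplsda(d$x, d$labels, n_ortho = n_ortho)
  schemes <- list(
    loo = cv_scheme("loo"),
    venetian_blinds = cv_scheme("venetian_blinds", n_splits = 10),
    contiguous_blocks = cv_scheme("contiguous_blocks", n_splits = 10),
    random_subsets = cv_scheme("random_subsets", n_splits = 10,
                               n_iterations = 10, seed = seed)
  )
  q2 <- vapply(schemes, function(s)
    oplsda_cv(d$x, d$labels, scheme = s, n_ortho = fit$n_ortho), 0)
  perm <- permutation_test(d$x, d$labels, scheme = cv_scheme("loo"),
                           n_ortho = fit$n_ortho, n_perm = n_perm,
                           seed = seed)
  list(R2Y = fit$R2Y, n_ortho = fit$n_ortho, Q2 = q2, permutation = perm)
}
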