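# Linear SVM: analytic solutions, oracle agreement with an independent
# solver (libsvm via e1071), metabolic-score conventions, LOOCV.

test_that("autoscaling centres to mean 0, SD 1 and is idempotent", {
  x <- cbind(a = c(1, 2, 3), b = c(10, 20, 60))
  sc <- autoscale(x)
  expect_equal(sc$x[, "a"], c(-1, 0, 1))
  expect_equal(unname(colMeans(sc$x)), c(0, 0))
  expect_equal(unname(apply(sc$x, 2, sd)), c(1, 1))
  # already-autoscaled input is unchanged
  sc2 <- autoscale(sc$x)
  expect_equal(sc2$x, sc$x, tolerance = 1e-12)
  expect_error(autoscale(cbind(a = c(1, 1, 1))), "zero-variance.*a")
})

test_that("class coding is fixed: N -> -1, C -> +1", {
  expect_equal(class_coding(c("C", "N", "C")), c(1, -1, 1))
  expect_error(class_coding(c("C", "X")), "'C' or 'N'")
})

test_that("separable data at large cost recovers the max-margin solution", {
  # 1-D points x = -1 (N), x = +1 (C): w = 1, b = 0 analytically
  x <- matrix(c(-1, 1), 2, 1, dimnames = list(NULL, "f1"))
  m <- train_linear_svm(x, c("N", "C"), cost = 1e4, scaling = FALSE)
  expect_equal(unname(m$w), 1, tolerance = 1e-6)
  expect_equal(m$b, 0, tolerance = 1e-6)
  # margin constraints c(wx' + b) >= 1 hold within tolerance
  set.seed(3)
  xs <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("f1", "f2")))
  yl <- rep(c("C", "N"), each = 10)
  xs[yl == "C", 1] <- xs[yl == "C", 1] + 6
  m2 <- train_linear_svm(xs, yl, cost = 1e4, scaling = FALSE, tol = 1e-8)
  marg <- class_coding(yl) * (drop(xs %*% m2$w) + m2$b)
  expect_true(all(marg >= 1 - 1e-6))
})

test_that("solution is invariant to duplication and antisymmetric to label flips", {
  set.seed(11)
  x <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("f1", "f2")))
  yl <- rep(c("C", "N"), 15)
  x[yl == "C", 1] <- x[yl == "C", 1] + 1.5
  m <- train_linear_svm(x, yl, cost = 1, scaling = FALSE, tol = 1e-8)
  # duplicating every point rescales the slack budget but not the margin;
  # duplicated data at half the cost reproduces the original solution
  m_dup2 <- train_linear_svm(rbind(x, x), c(yl, yl), cost = 0.5,
                             scaling = FALSE, tol = 1e-8)
  expect_equal(m_dup2$w, m$w, tolerance = 1e-4)
  expect_equal(m_dup2$b, m$b, tolerance = 1e-4)
  flip <- ifelse(yl == "C", "N", "C")
  m_f <- train_linear_svm(x, flip, cost = 1, scaling = FALSE, tol = 1e-8)
  expect_equal(m_f$w, -m$w, tolerance = 1e-5)
  expect_equal(m_f$b, -m$b, tolerance = 1e-5)
  expect_error(train_linear_svm(x, rep("C", 30)), "both classes")
})

test_that("solver agrees with an independent libsvm implementation", {
  skip_if_not_installed("e1071")
  for (s in 1:6) {
    set.seed(s)
    n <- 30 + 2 * s
    p <- 3 + s
    x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
    yl <- rep(c("C", "N"), length.out = n)
    x[yl == "C", 1] <- x[yl == "C", 1] + runif(1, 0.5, 2)
    cost <- c(0.1, 1, 10)[1 + s %% 3]
    mine <- train_linear_svm(x, yl, cost = cost, scaling = FALSE, tol = 1e-9)
    ref <- e1071_linear(x, yl, cost)
    expect_equal(unname(mine$w), unname(ref$w), tolerance = 1e-4)
    expect_equal(mine$b, ref$b, tolerance = 1e-4)
  }
})

test_that("metabolic score follows the sign convention and tie rule", {
  model <- structure(list(
    w = c(f1 = 1, f2 = -1), b = 0, feature_ids = c("f1", "f2"),
    scaling = list(center = c(f1 = 0, f2 = 0), scale = c(f1 = 1, f2 = 1)),
    cost = 1, n_support = 2), class = "svm_model")
  res <- metabolic_score(model, c(f1 = 2, f2 = 1))
  expect_equal(res$score, 1)
  expect_equal(res$class, "C")
  expect_equal(metabolic_score(model, c(f1 = 1, f2 = 3))$class, "N")
  # a sample exactly on the hyperplane is called N with a warning
  expect_warning(tie <- metabolic_score(model, c(f1 = 1, f2 = 1)),
                 "hyperplane")
  expect_equal(tie$class, "N")
  expect_error(metabolic_score(model, c(f1 = 1)), "missing model feature")
  # scaling is applied internally to raw-scale input
  model$scaling <- list(center = c(f1 = 10, f2 = 10),
                        scale = c(f1 = 2, f2 = 2))
  expect_equal(metabolic_score(model, c(f1 = 14, f2 = 10))$score, 2)
})

test_that("scores are antisymmetric under label flip", {
  sm <- make_class_matrix(n_per_class = 8, p = 4, delta = 2, seed = 4)
  flip <- sm
  flip$samples$class_label <- ifelse(sm$samples$class_label == "C", "N", "C")
  m1 <- train_linear_svm(sm)
  m2 <- train_linear_svm(flip)
  s1 <- metabolic_score(m1, sm$x)$score
  s2 <- metabolic_score(m2, sm$x)$score
  expect_equal(s1, -s2, tolerance = 1e-5)
})

test_that("LOOCV equals brute-force fold enumeration with an independent solver", {
  skip_if_not_installed("e1071")
  sm <- make_class_matrix(n_per_class = 6, p = 4, delta = 1.5, seed = 8)
  res <- loocv_evaluate(sm, cost = 1, scaling_mode = "global", tol = 1e-9)
  # oracle: explicit per-fold refits with e1071 on the globally scaled data
  xs <- scale(sm$x)
  yl <- sm$samples$class_label
  oracle_scores <- vapply(seq_len(nrow(xs)), function(i) {
    ref <- e1071_linear(xs[-i, , drop = FALSE], yl[-i], cost = 1)
    drop(xs[i, ] %*% ref$w) + ref$b
  }, 0)
  expect_equal(unname(res$scores), oracle_scores, tolerance = 1e-3)
  oracle_pred <- ifelse(oracle_scores > 0, "C", "N")
  expect_equal(res$accuracy, 100 * mean(oracle_pred == yl))
  expect_equal(res$sensitivity,
               100 * mean(oracle_pred[yl == "C"] == "C"))
  expect_equal(res$specificity,
               100 * mean(oracle_pred[yl == "N"] == "N"))
})

test_that("widely separated classes give perfect LOOCV; metrics are permutation-invariant", {
  x <- rbind(matrix(c(10, 10, 11, 11), 2, 2, byrow = TRUE),
             matrix(c(-10, -10, -11, -11), 2, 2, byrow = TRUE))
  colnames(x) <- c("f1", "f2")
  res <- loocv_evaluate(x, c("C", "C", "N", "N"), cost = 10)
  expect_equal(res$accuracy, 100)
  expect_equal(res$sensitivity, 100)
  expect_equal(res$specificity, 100)
  # feature permutation leaves the metrics unchanged
  sm <- make_class_matrix(n_per_class = 7, p = 5, delta = 1, seed = 12)
  perm <- sample_matrix(sm$x[, c(3, 1, 5, 2, 4)], sm$samples)
  expect_equal(loocv_evaluate(perm)$accuracy, loocv_evaluate(sm)$accuracy)
  expect_error(loocv_evaluate(x[1:3, ], c("C", "C", "N")), "at least 2")
})

test_that("LOOCV accuracy under random labels centres on 50%", {
  set.seed(77)
  accs <- replicate(200, {
    n <- 40
    x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
    yl <- sample(rep(c("C", "N"), each = n / 2))
    loocv_evaluate(x, yl, cost = 1)$accuracy
  })
  # LOOCV of noise is slightly pessimistic of 50%; Monte-Carlo band
  expect_gt(mean(accs), 35)
  expect_lt(mean(accs), 55)
})
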