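test_that("early fusion concatenates in fixed dimension order", {
  svs <- list(prosody = rep(3, 52), articulation = rep(1, 232),
              phonation = rep(2, 28))
  fused <- fuse_supervectors(svs)
  expect_length(fused, 312)
  expect_equal(fused, c(rep(1, 232), rep(2, 28), rep(3, 52)))
  # input order is irrelevant
  expect_equal(fuse_supervectors(rev(svs)), fused)
  expect_error(fuse_supervectors(svs[c("articulation", "phonation")]),
               "prosody")
})

test_that("z-scoring uses train statistics only and handles constants", {
  z <- zscore_fit_apply(matrix(c(1, 2, 3)), matrix(c(2, 4)))
  expect_equal(drop(z$train), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  # test is transformed with the train mean/sd, not its own
  expect_equal(drop(z$test), (c(2, 4) - 2) / sqrt(2 / 3), tolerance = 1e-12)
  # standardizing the standardized train again is not the identity transform
  z2 <- zscore_fit_apply(z$test)
  expect_false(isTRUE(all.equal(z2$train, z$test)))

  zc <- zscore_fit_apply(matrix(5, 4, 2))
  expect_true(all(zc$train == 0))
  expect_false(anyNA(zc$train))
})

test_that("PCA keeps the smallest k reaching the variance target", {
  set.seed(3)
  # variance concentrated in one direction
  base <- stats::rnorm(100)
  X <- cbind(base * 3, base * 3 + stats::rnorm(100, sd = 0.2),
             stats::rnorm(100, sd = 0.2))
  expect_equal(pca_reduce(X, var_kept = 0.9)$k, 1L)

  # isotropic data: oracle is the eigenvalue cumulative sum
  set.seed(4)
  Y <- matrix(stats::rnorm(2000), 200, 10)
  ev <- sort(eigen(stats::cov(Y))$values, decreasing = TRUE)
  oracle_k <- which(cumsum(ev) / sum(ev) >= 0.9)[1]
  expect_equal(pca_reduce(Y, var_kept = 0.9)$k, oracle_k)

  # reconstruction error decreases as more variance is kept
  err <- vapply(c(0.5, 0.9, 0.999), function(vk) {
    p <- pca_reduce(Y, var_kept = vk)
    rec <- p$train %*% t(p$rotation)
    sum((sweep(Y, 2, p$center) - rec)^2)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("confusion-matrix metrics follow the standard definitions", {
  m <- metrics_from_confusion(matrix(c(44, 8, 6, 42), 2), positive = 1)
  expect_equal(m$accuracy, 86)
  expect_equal(m$sensitivity, 88)
  expect_equal(m$specificity, 84)

  d <- metrics_from_confusion(diag(c(10, 20, 30)))
  expect_equal(c(d$accuracy, d$sensitivity, d$specificity), c(100, 100, 100))

  cm <- matrix(c(24, 2, 12, 9, 48, 6, 17, 0, 32), 3)
  expect_equal(unname(diag(cm) / rowSums(cm)), c(0.48, 0.96, 0.64))
  t3 <- metrics_from_confusion(cm)
  expect_equal(t3$sensitivity, 100 * mean(c(0.48, 0.96, 0.64)))
  expect_error(metrics_from_confusion(matrix(numeric(0), 0, 0)), "empty")
})

test_that("stratified folds deviate from global proportions by at most 1", {
  y <- factor(rep(c("a", "b", "c"), times = c(23, 31, 17)))
  for (seed in 1:3) {
    fold <- stratified_folds(y, 10, seed)
    tab <- table(fold, y)
    for (cl in levels(y))
      expect_lte(diff(range(tab[, cl])), 1)
  }
})

test_that("decision scores are sign-consistent with predictions", {
  set.seed(5)
  X <- matrix(stats::rnorm(120 * 6), 120) +
    outer(rep(c(0, 2, 4), each = 40), rep(1, 6))
  y <- factor(rep(c("a", "b", "c"), each = 40))
  m3 <- svm_ovr_fit(X, y, cost = 10, gamma = 0.1)
  s3 <- decision_scores(m3, X)
  expect_equal(dim(s3), c(120L, 3L))
  expect_equal(as.character(predict(m3, X)),
               colnames(s3)[max.col(s3)])

  yb <- factor(rep(c("a", "b"), each = 60))
  Xb <- X[c(1:60, 61:120), ]
  m2 <- svm_ovr_fit(Xb, yb, cost = 10, gamma = 0.1)
  s2 <- decision_scores(m2, Xb)
  expect_equal(ifelse(s2 >= 0, "a", "b"),
               as.character(predict(m2, Xb)))
})

test_that("separable classes reach 100 +/- 0 accuracy under repeated CV", {
  set.seed(6)
  X <- rbind(matrix(stats::rnorm(20 * 5), 20),
             matrix(stats::rnorm(20 * 5, mean = 10), 20))
  y <- factor(rep(c("a", "b"), each = 20))
  spec <- experiment_spec(folds = 10, repetitions = 3,
                          c_grid = c(0.1, 1, 10), gamma_grid = c(0.01, 0.1),
                          seed = 2)
  r <- run_experiment(X, y, spec)
  expect_equal(r$accuracy_mean, 100)
  expect_equal(r$accuracy_sd, 0)
  expect_equal(sum(r$confusion), 40)
  expect_equal(unname(rowSums(r$confusion)), c(20, 20))
})

test_that("identical seeds give identical cross-validation results", {
  set.seed(7)
  X <- matrix(stats::rnorm(60 * 4), 60)
  y <- factor(rep(c("a", "b"), each = 30))
  spec <- experiment_spec(folds = 5, repetitions = 2,
                          c_grid = c(0.1, 1), gamma_grid = c(0.1, 1),
                          seed = 3)
  r1 <- run_experiment(X, y, spec)
  r2 <- run_experiment(X, y, spec)
  expect_identical(r1$per_repetition_accuracy, r2$per_repetition_accuracy)
  expect_identical(r1$scores, r2$scores)
  expect_identical(r1$confusion, r2$confusion)
})

test_that("a class smaller than the fold count is refused by name", {
  X <- matrix(stats::rnorm(26), 13, 2)
  y <- factor(c(rep("big", 10), rep("tiny", 3)))
  expect_error(run_experiment(X, y, experiment_spec(folds = 10)), "tiny")
})

test_that("train-fitted transforms are unaffected by test-side content", {
  set.seed(8)
  tr <- matrix(stats::rnorm(50 * 6), 50)
  te1 <- matrix(stats::rnorm(10 * 6), 10)
  te2 <- matrix(stats::rnorm(10 * 6, mean = 100), 10)
  z1 <- zscore_fit_apply(tr, te1); z2 <- zscore_fit_apply(tr, te2)
  expect_identical(z1$center, z2$center)
  expect_identical(z1$scale, z2$scale)
  expect_identical(z1$train, z2$train)
  p1 <- pca_reduce(tr, te1); p2 <- pca_reduce(tr, te2)
  expect_identical(p1$rotation, p2$rotation)
  expect_identical(p1$k, p2$k)
})

test_that("LDA projection separates classes and degrades gracefully", {
  set.seed(9)
  X <- matrix(stats::rnorm(90 * 5), 90) +
    outer(rep(c(0, 5, 10), each = 30), rep(1, 5))
  y <- factor(rep(c("a", "b", "c"), each = 30))
  pr <- lda_project(X, y)
  expect_equal(dim(pr), c(90L, 2L))
  cent <- apply(pr, 2, function(col) tapply(col, y, mean))
  within_sd <- mean(tapply(pr[, 1], y, stats::sd))
  d_ab <- sqrt(sum((cent["a", ] - cent["b", ])^2))
  d_bc <- sqrt(sum((cent["b", ] - cent["c", ])^2))
  expect_gt(d_ab, within_sd)
  expect_gt(d_bc, within_sd)

  # duplicated columns: same projection up to sign
  pr2 <- lda_project(cbind(X, X), y)
  for (j in 1:2) {
    agree <- max(abs(pr2[, j] - pr[, j]), na.rm = TRUE)
    flip <- max(abs(pr2[, j] + pr[, j]), na.rm = TRUE)
    expect_lt(min(agree, flip), 1e-6)
  }

  # two classes: one discriminant, second coordinate zero
  y2 <- factor(rep(c("a", "b"), 45))
  pr3 <- lda_project(X, y2)
  expect_true(all(pr3[, 2] == 0))
})
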