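test_that("soft counts total the frame count; M = 1 gives sample moments", {
  m <- random_gmm(3, 2, 1)
  X <- sample_gmm(m, 200, seed = 2)
  st <- sufficient_stats(X, m)
  expect_equal(sum(st$n), 200, tolerance = 1e-8)
  expect_true(all(st$n >= 0))

  one <- gmm(1, matrix(c(0, 0), 1), matrix(c(1, 1), 1))
  st1 <- sufficient_stats(X, one)
  expect_equal(st1$first_moment[1, ], colMeans(X), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(st1$second_moment[1, ], colMeans(X^2), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("sufficient statistics match a brute-force double loop", {
  m <- random_gmm(3, 2, 3)
  set.seed(4)
  X <- matrix(stats::rnorm(100, sd = 2), 50, 2)
  st <- sufficient_stats(X, m)

  pr <- matrix(0, 50, 3)
  for (t in 1:50) {
    u <- vapply(1:3, function(i)
      m$weights[i] * prod(stats::dnorm(X[t, ], m$means[i, ],
                                       sqrt(m$variances[i, ]))),
      numeric(1))
    pr[t, ] <- u / sum(u)
  }
  n <- colSums(pr)
  ex <- matrix(0, 3, 2); ex2 <- matrix(0, 3, 2)
  for (i in 1:3) for (d in 1:2) {
    ex[i, d] <- sum(pr[, i] * X[, d]) / n[i]
    ex2[i, d] <- sum(pr[, i] * X[, d]^2) / n[i]
  }
  expect_equal(st$n, n, tolerance = 1e-9)
  expect_equal(st$first_moment, ex, tolerance = 1e-9)
  expect_equal(st$second_moment, ex2, tolerance = 1e-9)
})

test_that("MAP adaptation: identity with no data, UBM limit as r grows", {
  ubm <- random_gmm(4, 3, 5)
  zero_stats <- structure(list(n = rep(0, 4), first_moment = ubm$means,
                               second_moment = ubm$variances + ubm$means^2,
                               T = 1L), class = "sufficient_stats")
  ad0 <- map_adapt(ubm, zero_stats)
  expect_equal(ad0$weights, ubm$weights, tolerance = 1e-14)
  expect_equal(ad0$means, ubm$means, tolerance = 1e-14)
  expect_equal(ad0$variances, ubm$variances, tolerance = 1e-14)

  X <- sample_gmm(ubm, 300, seed = 6)
  st <- sufficient_stats(X, ubm)
  far <- map_adapt(ubm, st, adaptation_config(relevance_factor = 1e12))
  expect_lt(max(abs(far$means - ubm$means)), 1e-6)
  expect_lt(max(abs(far$weights - ubm$weights)), 1e-6)
})

test_that("adaptive coefficient: alpha = 1/2 exactly at n = r, monotone", {
  ubm <- random_gmm(3, 2, 7)
  st <- structure(list(n = c(16, 4, 100),
                       first_moment = ubm$means,
                       second_moment = ubm$variances + ubm$means^2,
                       T = 120L), class = "sufficient_stats")
  ad <- map_adapt(ubm, st, adaptation_config(relevance_factor = 16))
  expect_equal(ad$meta$alpha, c(0.5, 4 / 20, 100 / 116), tolerance = 1e-14)
  # strictly increasing in n
  n_grid <- c(0, 1, 4, 16, 64, 1e4)
  expect_true(all(diff(n_grid / (n_grid + 16)) > 0))
})

test_that("M = 1 mean update follows the closed form", {
  ubm <- gmm(1, matrix(0), matrix(1))
  X <- matrix(stats::rnorm(10000), ncol = 1)
  st <- sufficient_stats(X, ubm)
  ad <- map_adapt(ubm, st, adaptation_config(relevance_factor = 16))
  alpha <- 10000 / (10000 + 16)
  expect_equal(ad$means[1, 1], alpha * mean(X), tolerance = 1e-12)
  expect_lt(abs(ad$means[1, 1] - mean(X)), 0.05)
})

test_that("adapted weights sum to one and means interpolate", {
  ubm <- random_gmm(4, 3, 8)
  for (seed in 1:4) {
    X <- sample_gmm(ubm, 150, seed = seed)
    X <- X + 0.5                                 # shift off the UBM
    st <- sufficient_stats(X, ubm)
    ad <- map_adapt(ubm, st)
    expect_equal(sum(ad$weights), 1, tolerance = 1e-12)
    # each adapted mean lies between the UBM mean and the data moment
    lo <- pmin(ubm$means, st$first_moment) - 1e-12
    hi <- pmax(ubm$means, st$first_moment) + 1e-12
    expect_true(all(ad$means >= lo & ad$means <= hi))
  }
})

test_that("supervector layout and length are 2 M D with means first", {
  m4 <- random_gmm(4, 13, 9)
  sv <- build_supervector(m4)
  expect_length(sv, 2 * 4 * 13)
  expect_equal(as.numeric(sv)[1:13], m4$means[1, ], ignore_attr = TRUE)
  expect_equal(as.numeric(sv)[(4 * 13 + 1):(4 * 13 + 13)],
               m4$variances[1, ], ignore_attr = TRUE)
  expect_true(all(as.numeric(sv)[(4 * 13 + 1):(2 * 4 * 13)] > 0))

  m2 <- random_gmm(2, 58, 10)
  expect_length(build_supervector(m2), 232)
})

test_that("adaptation is deterministic and shifts toward shifted data", {
  ubm <- random_gmm(3, 4, 11)
  X <- sample_gmm(ubm, 400, seed = 12)
  s1 <- adapt_recording(X, ubm)
  s2 <- adapt_recording(X, ubm)
  expect_identical(as.numeric(s1), as.numeric(s2))

  # +delta on coordinate 1: every well-populated component mean moves up
  delta <- 2
  Xs <- X; Xs[, 1] <- Xs[, 1] + delta
  st <- sufficient_stats(Xs, ubm)
  ad <- map_adapt(ubm, st)
  heavy <- st$n > 16
  expect_true(any(heavy))
  expect_true(all(ad$means[heavy, 1] > ubm$means[heavy, 1]))

  expect_error(adapt_recording(matrix(numeric(0), 0, 4), ubm), "frames")
})
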