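test_that("window count follows the floor((T - W)/step) convention", {
  expect_identical(n_windows(253, 22, 1), 231L)
  expect_identical(n_windows(12, 10, 1), 2L)
  expect_error(n_windows(22, 22, 1), "smaller than")
})

test_that("taper weights are a renormalised rectangle-Gaussian convolution", {
  w <- taper_weights(22, 3)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(w, rev(w), tolerance = 1e-12)
  expect_true(all(w > 0))

  # vanishing sigma degenerates to the uniform window
  expect_lt(max(abs(taper_weights(22, 0.01) - 1 / 22)), 1e-6)

  # brute-force double-loop convolution oracle
  sigma <- 3
  half <- ceiling(3 * sigma)
  kern <- dnorm(-half:half, sd = sigma)
  kern <- kern / sum(kern)
  wlen <- 22L
  full <- numeric(wlen + 2 * half)
  for (i in seq_along(full)) {
    for (j in seq_len(wlen)) {
      ki <- i - j + 1L
      if (ki >= 1L && ki <= length(kern)) full[i] <- full[i] + kern[ki]
    }
  }
  oracle <- full[(half + 1):(half + wlen)]
  oracle <- oracle / sum(oracle)
  expect_equal(w, oracle, tolerance = 1e-12)

  expect_error(taper_weights(22, 0), "sigma")
})

test_that("windowed FC reduces to tapered correlation at zero penalty and to the identity at huge penalty", {
  ts <- make_ts(50, 5, seed = 6)
  wf0 <- windowed_fc(ts, 20, 3, 1, lambda = 0)
  expect_length(wf0$matrices, n_windows(50, 20, 1))
  # manual tapered correlation of the first window
  wts <- taper_weights(20, 3)
  x <- ts$data[1:20, ]
  mu <- colSums(x * wts)
  xc <- sweep(x, 2, mu)
  cv <- crossprod(xc * sqrt(wts), xc * sqrt(wts))
  cr <- cov2cor(cv)
  diag(cr) <- 0
  expect_equal(unname(wf0$matrices[[1]]), unname(cr), tolerance = 1e-6,
               ignore_attr = TRUE)

  wf_big <- windowed_fc(ts, 20, 3, 1, lambda = 1000)
  expect_lt(max(abs(wf_big$matrices[[5]])), 1e-6)

  expect_error(windowed_fc(ts, 20, 3, 1, lambda = -0.1), "non-negative")
})

test_that("windowed matrices are symmetric, bounded, and permutation-equivariant", {
  ts <- make_ts(60, 6, seed = 12)
  wf <- windowed_fc(ts, 20, 3, 2, lambda = 0.1)
  for (m in wf$matrices) {
    expect_equal(m, t(m), tolerance = 1e-10)
    expect_lt(max(abs(m)), 1 + 1e-10)
  }
  perm <- c(3L, 1L, 6L, 2L, 5L, 4L)
  ts_p <- subject_ts(ts$data[, perm], 2.7)
  wf_p <- windowed_fc(ts_p, 20, 3, 2, lambda = 0.1)
  expect_equal(unname(wf_p$matrices[[4]]),
               unname(wf$matrices[[4]][perm, perm]), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("penalised precision matches the reference estimator on a fixed fixture", {
  # 12 x 5 integer design; reference values from an independent
  # graphical-lasso implementation on cor(X) at lambda = 0.1
  X <- matrix(c(
    2, 5, 1, 7, 3,  4, 1, 6, 2, 8,  7, 3, 2, 5, 1,  1, 8, 4, 3, 6,
    5, 2, 7, 1, 4,  3, 6, 1, 8, 2,  8, 4, 5, 2, 7,  2, 7, 3, 6, 1,
    6, 1, 8, 4, 5,  4, 5, 2, 7, 3,  1, 3, 6, 2, 8,  7, 2, 4, 5, 1),
    nrow = 12, ncol = 5, byrow = TRUE)
  oracle <- matrix(c(
    1.34591476, 0.69176712, 0.00000000, 0.00000000, 0.23988226,
    0.69176712, 1.76320402, 0.81421858, 0.00000000, 0.00000000,
    0.00000000, 0.81421858, 2.62774851, 1.43165756, -0.29240440,
    0.00000000, 0.00000000, 1.43165756, 2.59971183, 0.88820145,
    0.23988226, 0.00000000, -0.29240440, 0.88820145, 1.72573263),
    5, 5, byrow = TRUE)
  fit <- graphical_lasso(cor(X), 0.1)
  expect_lt(max(abs(unname(fit$precision) - oracle)), 5e-3)
  # estimated covariance inverts the precision
  expect_lt(max(abs(fit$cov %*% fit$precision - diag(5))), 1e-4)
})

test_that("precision sparsity is monotone along the penalty grid", {
  ts <- make_ts(40, 8, seed = 20)
  s <- window_covariances(ts, 30, 3, 1)[[1]]
  nnz <- vapply(c(0.01, 0.03, 0.1, 0.3, 0.5), function(lam) {
    th <- graphical_lasso(s, lam)$precision
    sum(abs(th[upper.tri(th)]) > 1e-8)
  }, 0L)
  expect_true(all(diff(nnz) <= 0))
})

test_that("windowed means recover static FC for a stationary subject", {
  sig <- small_corr(5)
  ts <- make_ts(5000, 5, seed = 14, sigma = sig)
  wf <- windowed_fc(ts, 22, 3, 10, lambda = 0)
  avg <- Reduce(`+`, wf$matrices) / length(wf$matrices)
  expect_lt(max(abs(avg - static_fc(ts))), 0.05)
})

test_that("penalty selection is deterministic and honours its grid", {
  ts <- make_ts(80, 6, seed = 17)
  covs <- window_covariances(ts, 20, 3, 4)
  expect_equal(select_lambda(covs, grid = 0.2)$lambda, 0.2)
  s1 <- select_lambda(covs, grid = c(0.01, 0.1, 0.5), n_reps = 5, seed = 3)
  s2 <- select_lambda(covs, grid = c(0.01, 0.1, 0.5), n_reps = 5, seed = 3)
  expect_identical(s1$lambda, s2$lambda)
  expect_error(select_lambda(covs, grid = numeric(0)), "empty")

  # on data from a sparse precision, the selected penalty's held-out score
  # is at least that of both grid extremes
  set.seed(8)
  theta <- diag(6)
  theta[1, 2] <- theta[2, 1] <- 0.4
  theta[3, 4] <- theta[4, 3] <- -0.35
  sig <- cov2cor(solve(theta))
  ts_sp <- make_ts(120, 6, seed = 19, sigma = sig)
  covs_sp <- window_covariances(ts_sp, 20, 3, 2)
  sel <- select_lambda(covs_sp, grid = c(0.01, 0.05, 0.1, 0.3, 0.6),
                       n_reps = 6, seed = 5)
  means <- rowMeans(sel$scores)
  expect_gte(means[as.character(sel$lambda)], means[[1]])
  expect_gte(means[as.character(sel$lambda)], means[[length(means)]])
})
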