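# two well-separated window regimes for planted-partition tests
make_window_set <- function(n1 = 30L, n2 = 30L, r = 6L, seed = 1L,
                            noise = 0.02) {
  set.seed(seed)
  t1 <- small_corr(r, within = 0.7, between = 0.4)
  t2 <- small_corr(r, within = 0.2, between = 0.02)
  jitter_mat <- function(m) {
    e <- matrix(rnorm(r * r, 0, noise), r)
    e <- (e + t(e)) / 2
    out <- pmin(pmax(m + e, -0.99), 0.99)
    diag(out) <- 0
    out
  }
  w1 <- lapply(seq_len(n1), function(i) jitter_mat(t1))
  w2 <- lapply(seq_len(n2), function(i) jitter_mat(t2))
  list(windows = c(w1, w2), truth = rep(c(1L, 2L), c(n1, n2)))
}

test_that("planted two-regime windows are recovered with k = 2 and exact labels", {
  ws <- make_window_set(seed = 4)
  dec <- cluster_states(list(subjA = ws$windows[1:30],
                             subjB = ws$windows[31:60]),
                        k_range = 2:4, reps = 10, seed = 2)
  expect_identical(dec$k, 2L)
  expect_identical(which.max(dec$silhouette_by_k), c(`2` = 1L))
  est <- unlist(dec$labels, use.names = FALSE)
  acc <- max(mean(est == ws$truth), mean((3L - est) == ws$truth))
  expect_equal(acc, 1)
  # ordering convention: state 1 is the more connected centroid
  conn <- vapply(dec$centroid_matrices,
                 function(m) mean(m[upper.tri(m)]), 0)
  expect_gt(conn[1], conn[2])
})

test_that("degenerate and permuted inputs behave per contract", {
  m <- small_corr(5)
  diag(m) <- 0
  expect_error(cluster_states(list(s = rep(list(m), 20)), k_range = 2:3,
                              reps = 3, seed = 1),
               "distinct")

  ws <- make_window_set(seed = 9)
  perm <- sample(seq_along(ws$windows))
  d1 <- cluster_states(list(all = ws$windows), k_range = 2:2, reps = 8,
                       seed = 3)
  d2 <- cluster_states(list(all = ws$windows[perm]), k_range = 2:2,
                       reps = 8, seed = 3)
  unperm <- integer(length(perm))
  unperm[perm] <- seq_along(perm)
  expect_identical(d1$labels$all, d2$labels$all[unperm])
})

test_that("mean silhouette matches direct evaluation and sign conventions", {
  x <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  lab <- c(1L, 1L, 2L, 2L)
  s <- silhouette_mean(x, lab)
  # independent hand evaluation
  D <- as.matrix(dist(x))
  svals <- vapply(1:4, function(i) {
    own <- which(lab == lab[i] & seq_len(4) != i)
    oth <- which(lab != lab[i])
    a <- mean(D[i, own])
    b <- mean(D[i, oth])
    (b - a) / max(a, b)
  }, 0)
  expect_equal(s, mean(svals), tolerance = 1e-12)
  expect_gt(s, 0.985)

  expect_lt(silhouette_mean(x, c(2L, 2L, 1L, 1L)[c(1, 3, 2, 4)]), 0)
  expect_error(silhouette_mean(x, rep(1L, 4)), "2 clusters")
})

test_that("mean silhouette agrees with the cluster package", {
  skip_if_not_installed("cluster")
  set.seed(6)
  x <- matrix(rnorm(60 * 3), 60)
  lab <- kmeans(x, 3, nstart = 5)$cluster
  ours <- silhouette_mean(x, lab)
  ref <- mean(cluster::silhouette(lab, dist(x))[, "sil_width"])
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("spherical BIC prefers the planted number of blobs and scales sanely", {
  set.seed(7)
  x <- rbind(matrix(rnorm(80, 0, 0.3), ncol = 2),
             matrix(rnorm(80, 6, 0.3), ncol = 2))
  lab2 <- rep(1:2, each = 40)
  cent2 <- rbind(colMeans(x[1:40, ]), colMeans(x[41:80, ]))
  bic1 <- bic_for_k(x, rep(1L, 80), t(colMeans(x)))
  bic2 <- bic_for_k(x, lab2, cent2)
  expect_lt(bic2, bic1)

  # duplicating every point leaves the argmin k unchanged
  xd <- rbind(x, x)
  b1 <- bic_for_k(xd, rep(1L, 160), t(colMeans(xd)))
  b2 <- bic_for_k(xd, rep(lab2, 2), cent2)
  expect_lt(b2, b1)

  expect_error(bic_for_k(x[1:2, ], 1:2, x[1:2, ]), "degenerate")
})

test_that("state medians are element-wise and tolerate unvisited states", {
  m <- small_corr(4)
  diag(m) <- 0
  expect_equal(state_medians(rep(list(m), 3), c(1L, 1L, 1L), k = 2)[[1]], m)
  expect_null(state_medians(rep(list(m), 3), c(1L, 1L, 1L), k = 2)[[2]])

  w <- lapply(c(0.1, 0.5, 0.9), function(v) {
    x <- m
    x[1, 2] <- x[2, 1] <- v
    x
  })
  med <- state_medians(w, c(1L, 1L, 1L), k = 1)[[1]]
  expect_equal(med[1, 2], 0.5)
})

test_that("temporal statistics enumerate runs, dwell and transitions", {
  t1 <- temporal_stats(c(1L, 1L, 2L, 2L, 2L, 1L), k = 2, tr_seconds = 2.7,
                       step_tr = 1)
  expect_identical(t1$n_transitions, 2L)
  expect_equal(unname(t1$fraction_time), c(0.5, 0.5))
  expect_equal(unname(t1$mean_dwell_min),
               c(1.5, 3) * 2.7 / 60, tolerance = 1e-12)

  t2 <- temporal_stats(rep(1L, 231), k = 2)
  expect_identical(t2$n_transitions, 0L)
  expect_equal(unname(t2$fraction_time), c(1, 0))
  expect_equal(unname(t2$mean_dwell_min[1]), 231 * 2.7 / 60)
  expect_true(is.na(t2$mean_dwell_min[2]))

  t3 <- temporal_stats(rep(c(1L, 2L), 3), k = 2)
  expect_identical(t3$n_transitions, 5L)

  expect_error(temporal_stats(integer(0)), "empty")
})

test_that("state decomposition lowers between-subject edge variance below static FC", {
  ch <- generate_cohort(n_subjects = 12, t_points = 253, seed = 41)
  wl <- lapply(ch$ts, function(ts) windowed_fc(ts, 22, 3, 1, 0.1)$matrices)
  dec <- cluster_states(wl, k_range = 2:2, reps = 5, seed = 6)
  static_mats <- lapply(ch$ts, static_fc)
  v_static <- edgewise_variance(static_mats)$mean_variance
  for (s in 1:2) {
    mats <- Filter(Negate(is.null),
                   lapply(dec$state_matrices, `[[`, s))
    if (length(mats) >= 2) {
      expect_lt(edgewise_variance(mats)$mean_variance, v_static)
    }
  }
})
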