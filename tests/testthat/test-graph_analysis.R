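path_graph <- function(n) {
  a <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) a[i, i + 1] <- a[i + 1, i] <- 1L
  a
}

star_graph <- function(n) {
  a <- matrix(0L, n, n)
  a[1, 2:n] <- a[2:n, 1] <- 1L
  a
}

cycle_graph <- function(n) {
  a <- path_graph(n)
  a[1, n] <- a[n, 1] <- 1L
  a
}

test_that("proportional thresholding keeps the right edge count with nested, deterministic sets", {
  set.seed(2)
  m <- matrix(rnorm(100), 10)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  a20 <- proportional_threshold(m, 20)
  expect_equal(sum(a20[upper.tri(a20)]), round(0.2 * 45)) # 9 edges
  expect_equal(a20, t(a20))
  expect_equal(unname(diag(a20)), rep(0L, 10))

  a10 <- proportional_threshold(m, 10)
  a34 <- proportional_threshold(m, 34)
  expect_true(all(a10[a10 == 1] <= a34[a10 == 1])) # nestedness

  # all-equal weights: the lexicographically first pairs win
  me <- matrix(1, 5, 5)
  diag(me) <- 0
  ae <- proportional_threshold(me, 30) # round(0.3*10) = 3 edges
  ut <- which(upper.tri(me))
  kept <- which(ae[upper.tri(ae)] == 1)
  expect_identical(kept, 1:3)

  expect_error(proportional_threshold(m, 0), "0, 100")
  expect_error(proportional_threshold(m, 100), "0, 100")

  # edge counts exact at every grid point
  for (p in seq(10, 34, by = 1)) {
    ap <- proportional_threshold(m, p)
    expect_equal(sum(ap[upper.tri(ap)]), floor(p / 100 * 45 + 0.5))
  }
})

test_that("global efficiency handles canonical graphs", {
  k4 <- matrix(1L, 4, 4)
  diag(k4) <- 0L
  expect_equal(global_efficiency(k4), 1)
  expect_equal(global_efficiency(path_graph(3)), 5 / 6)
  expect_equal(global_efficiency(matrix(0L, 4, 4)), 0)
})

test_that("assortativity, clustering and betweenness honour canonical values", {
  st <- star_graph(5)
  expect_equal(assortativity_degree_bin(st), -1)
  expect_warning(val <- assortativity_degree_bin(cycle_graph(6)),
                 "undefined")
  expect_true(is.na(val))
  expect_error(assortativity_degree_bin(matrix(0L, 4, 4)), "edgeless")

  tri <- matrix(1L, 3, 3)
  diag(tri) <- 0L
  expect_equal(clustering_coefficients(tri), rep(1, 3), ignore_attr = TRUE)
  expect_equal(clustering_coefficients(path_graph(3))[2], 0,
               ignore_attr = TRUE)

  bst <- betweenness_centrality(st)
  expect_equal(bst[1], 1, ignore_attr = TRUE)
  expect_equal(bst[-1], rep(0, 4), ignore_attr = TRUE)
  expect_equal(betweenness_centrality(cycle_graph(4)),
               rep(1 / 6, 4), ignore_attr = TRUE)
  expect_error(betweenness_centrality(matrix(0L, 2, 2)), "3 nodes")
})

test_that("all four metrics match brute-force oracles on 100 random graphs", {
  worst <- 0
  for (i in 1:100) {
    r <- sample(4:12, 1)
    a <- random_adjacency(r, p_edge = runif(1, 0.2, 0.6), seed = 1000 + i)
    if (sum(a) == 0) next
    worst <- max(worst,
                 abs(global_efficiency(a) - bf_global_efficiency(a)),
                 max(abs(clustering_coefficients(a) - bf_clustering(a))),
                 max(abs(betweenness_centrality(a) - bf_betweenness(a))))
    got <- suppressWarnings(assortativity_degree_bin(a))
    ref <- bf_assortativity(a)
    if (is.na(ref)) {
      expect_true(is.na(got))
    } else {
      worst <- max(worst, abs(got - ref))
    }
  }
  expect_lt(worst, 1e-9)
})

test_that("assortativity agrees with igraph on random graphs", {
  for (i in 1:40) {
    a <- random_adjacency(sample(5:14, 1), p_edge = runif(1, 0.2, 0.6),
                          seed = 7000 + i)
    if (sum(a) == 0) next
    ref <- suppressWarnings(igraph::assortativity_degree(
      igraph::graph_from_adjacency_matrix(a != 0, mode = "undirected")))
    got <- suppressWarnings(assortativity_degree_bin(a))
    if (is.nan(ref)) {
      expect_true(is.na(got))
    } else {
      expect_equal(got, ref, tolerance = 1e-12)
    }
  }
})

test_that("small-worldness separates lattice-with-shortcuts from dense random graphs", {
  # ring lattice, degree 6, with a few rewired shortcuts
  n <- 50L
  a <- matrix(0L, n, n)
  for (d in 1:3) {
    for (i in 1:n) {
      j <- ((i + d - 1) %% n) + 1
      a[i, j] <- a[j, i] <- 1L
    }
  }
  set.seed(3)
  for (rep in 1:8) { # rewire ~5% of edges into shortcuts
    i <- sample(n, 1)
    nb <- which(a[i, ] == 1)
    j <- sample(nb, 1)
    far <- which(a[i, ] == 0 & seq_len(n) != i)
    k <- sample(far, 1)
    a[i, j] <- a[j, i] <- 0L
    a[i, k] <- a[k, i] <- 1L
  }
  sw <- small_worldness(a, n_null = 20, seed = 7)
  expect_gt(sw, 1)

  dense <- random_adjacency(50, p_edge = 0.5, seed = 99)
  swd <- small_worldness(dense, n_null = 20, seed = 7)
  expect_lt(abs(swd - 1), 0.2)

  expect_identical(small_worldness(a, n_null = 10, seed = 5),
                   small_worldness(a, n_null = 10, seed = 5))
  expect_error(small_worldness(matrix(0L, 4, 4)), "edgeless")
})

test_that("threshold AUC integrates trapezoids and skips missing segments", {
  thr <- seq(10, 34, by = 1)
  expect_equal(metric_auc(rep(1, 25), thr), 0.24)
  ramp <- seq(0, 1, length.out = 25)
  expect_equal(metric_auc(ramp, thr), 0.12)

  v <- ramp
  v[10] <- NA
  # independent segment-sum oracle over consecutive defined pairs
  x <- thr / 100
  acc <- 0
  for (i in 1:24) {
    if (!is.na(v[i]) && !is.na(v[i + 1])) {
      acc <- acc + (x[i + 1] - x[i]) * (v[i] + v[i + 1]) / 2
    }
  }
  expect_equal(suppressWarnings(metric_auc(v, thr)), acc, tolerance = 1e-12)
  expect_warning(metric_auc(v, thr), "missing")
  expect_error(metric_auc(1, 10), "2 thresholds")
})

test_that("a profile evaluates 25 graphs and respects node relabelling", {
  # distinct edge weights so the deterministic tie-break cannot differ
  # between orderings
  set.seed(44)
  m <- small_corr(8, within = 0.6, between = 0.15)
  jit <- matrix(runif(64, -0.01, 0.01), 8)
  m <- m + (jit + t(jit)) / 2
  diag(m) <- 0
  prof <- profile_for_matrix(m, metrics = c("global_efficiency",
                                            "assortativity", "clustering",
                                            "betweenness"))
  expect_identical(prof$n_graphs, 25L)
  expect_length(prof$auc$clustering, 8L)

  perm <- c(5L, 2L, 8L, 1L, 7L, 3L, 6L, 4L)
  prof_p <- profile_for_matrix(m[perm, perm],
                               metrics = c("global_efficiency",
                                           "assortativity", "clustering",
                                           "betweenness"))
  expect_equal(prof_p$auc$global_efficiency, prof$auc$global_efficiency,
               tolerance = 1e-12)
  expect_equal(unname(prof_p$auc$betweenness),
               unname(prof$auc$betweenness[perm]), tolerance = 1e-12)

  prof2 <- profile_for_matrix(m, metrics = c("global_efficiency",
                                             "assortativity", "clustering",
                                             "betweenness"))
  expect_identical(prof$auc, prof2$auc)
})

test_that("global efficiency is non-decreasing along the threshold sweep", {
  set.seed(10)
  m <- matrix(rnorm(144), 12)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  eff <- vapply(seq(10, 34, 1), function(p) {
    global_efficiency(proportional_threshold(m, p))
  }, 0)
  expect_true(all(diff(eff) >= -1e-12))
})
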