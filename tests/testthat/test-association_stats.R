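test_that("DBS response is the percent UPDRS-III improvement", {
  expect_equal(round(dbs_response(27.1, 12.8), 2), 52.77)
  expect_equal(dbs_response(10, 10), 0)
  expect_equal(dbs_response(20, 0), 100)
  expect_error(dbs_response(0, 5), "positive")
})

test_that("partial correlation matches the residualisation oracle", {
  set.seed(4)
  n <- 20
  z <- cbind(z1 = rnorm(n), z2 = runif(n))
  x <- 0.5 * z[, 1] + rnorm(n)
  y <- -0.3 * z[, 1] + 0.4 * x + rnorm(n)
  pc <- partial_correlation(x, y, z)
  rx <- resid(lm(x ~ z))
  ry <- resid(lm(y ~ z))
  expect_equal(pc$r, cor(rx, ry), tolerance = 1e-10)
  # t statistic with df corrected for the 2 covariates
  tval <- pc$r * sqrt(pc$df / (1 - pc$r^2))
  expect_equal(pc$p, 2 * pt(-abs(tval), n - 4), tolerance = 1e-12)
  expect_true(pc$ci[1] <= pc$r && pc$r <= pc$ci[2])

  # reductions and invariances
  expect_equal(partial_correlation(x, y, NULL)$r, cor(x, y),
               tolerance = 1e-12)
  expect_equal(partial_correlation(x, x, z)$r, 1, tolerance = 1e-12)
  aff <- partial_correlation(3 * x - 1, -2 * y + 5, cbind(10 * z[, 1] + 2,
                                                          z[, 2]))
  expect_equal(abs(aff$r), abs(pc$r), tolerance = 1e-10)

  expect_error(partial_correlation(x, y, cbind(z, z[, 1])),
               "rank-deficient")
  expect_error(partial_correlation(x[1:4], y[1:4], z[1:4, ]),
               "insufficient")
})

test_that("BH adjustment reproduces the step-up rule and preserves ranking", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(0.37), 0.37)

  set.seed(11)
  p <- runif(25)^2
  adj <- fdr_bh(p)
  # hand step-up oracle
  o <- order(p)
  n <- length(p)
  stepped <- rev(cummin(rev(p[o] * n / seq_len(n))))
  oracle <- pmin(stepped, 1)[order(o)]
  expect_equal(adj, oracle, tolerance = 1e-12)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[o]) >= -1e-15)) # ranking preserved

  expect_error(fdr_bh(c(0.5, 0)), "0, 1")
  expect_error(fdr_bh(c(0.5, 1.2)), "0, 1")
})

test_that("association table assembles families with FDR and pairwise exclusion", {
  set.seed(21)
  n <- 12
  ids <- sprintf("s%02d", 1:n)
  mk_prof <- function(seed) {
    set.seed(seed)
    list(auc = list(global_efficiency = runif(1, 0.3, 0.6),
                    assortativity = runif(1, -0.3, 0.3),
                    clustering = setNames(runif(4), paste0("n", 1:4)),
                    betweenness = setNames(runif(4), paste0("n", 1:4))))
  }
  profiles <- list(
    static = setNames(lapply(1:n, function(i) mk_prof(i)), ids),
    state1 = setNames(lapply(1:n, function(i) mk_prof(100 + i)), ids),
    # one subject never visits state 2
    state2 = setNames(lapply(1:(n - 1), function(i) mk_prof(200 + i)),
                      ids[1:(n - 1)]))
  response <- setNames(runif(n, 20, 80), ids)
  ofc <- setNames(runif(n, 0.2, 0.5), ids)
  temporal <- setNames(lapply(1:n, function(i) {
    set.seed(300 + i)
    ft <- runif(1, 0.2, 0.8)
    list(fraction_time = c(ft, 1 - ft),
         mean_dwell_min = runif(2, 0.5, 4),
         n_transitions = sample(1:8, 1))
  }), ids)
  res <- associate(profiles, response, ofc, temporal = temporal, min_n = 8)

  glob <- res[res$metric %in% c("global_efficiency", "assortativity"), ]
  expect_identical(nrow(glob), 6L) # 2 metrics x 3 conditions
  expect_true(all(res$p_fdr >= res$p_value - 1e-12))
  expect_true(all(abs(res$r_partial) <= 1))
  expect_true(all(res$ci_low <= res$r_partial & res$r_partial <= res$ci_high))
  # pairwise exclusion recorded for the metric families of state 2
  met <- res$metric %in% c("global_efficiency", "assortativity",
                           "clustering", "betweenness")
  expect_identical(unique(res$n_used[met & res$state == "state2"]),
                   as.integer(n - 1))
  # local families FDR-corrected per metric x state
  loc <- res[res$metric == "clustering" & res$state == "static", ]
  expect_identical(nrow(loc), 4L)
  expect_equal(loc$p_fdr, fdr_bh(loc$p_value))
  # temporal rows present and uncorrected
  expect_true(any(res$metric == "fraction_time"))
  expect_true(any(res$metric == "n_transitions"))

  expect_error(associate(profiles, setNames(rep(50, n), ids), ofc),
               "zero variance")
})

test_that("a planted association survives a permutation null", {
  ch <- generate_cohort(n_subjects = 60, planted_r = -0.7,
                        simulate_timeseries = FALSE, seed = 17)
  auc <- ch$truth$true_assortativity_auc
  resp <- ch$truth$response
  obs <- abs(partial_correlation(auc, resp, NULL)$r)
  set.seed(9)
  exceed <- mean(replicate(200, {
    abs(partial_correlation(auc, sample(resp), NULL)$r) >= obs
  }))
  expect_lt(exceed, 0.05) # permutation p-value of the planted effect
})
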