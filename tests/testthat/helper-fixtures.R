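# Fixtures and independent brute-force oracles used across the suite.

# small positive-definite correlation matrix with block structure
small_corr <- function(r = 6L, within = 0.5, between = 0.1, blocks = 2L) {
  grp <- rep(seq_len(blocks), length.out = r)
  m <- matrix(between, r, r)
  m[outer(grp, grp, `==`)] <- within
  diag(m) <- 1
  e <- eigen(m, symmetric = TRUE)
  v <- pmax(e$values, 1e-3)
  m <- e$vectors %*% (v * t(e$vectors))
  m <- cov2cor(m)
  dimnames(m) <- list(paste0("r", 1:r), paste0("r", 1:r))
  m
}

make_ts <- function(t_points = 40L, r = 6L, seed = 1L, sigma = NULL,
                    id = "s01") {
  set.seed(seed)
  if (is.null(sigma)) sigma <- small_corr(r)
  x <- matrix(rnorm(t_points * nrow(sigma)), t_points) %*% chol(sigma)
  colnames(x) <- colnames(sigma)
  subject_ts(x, tr_seconds = 2.7, subject_id = id)
}

make_phenotypes <- function(ids, seed = 1L) {
  set.seed(seed)
  n <- length(ids)
  onoff <- round(runif(n, 15, 50), 1)
  data.frame(subject_id = ids,
             age_years = round(runif(n, 45, 70), 1),
             gender = rbinom(n, 1, 0.3),
             updrs3_on_preop = round(runif(n, 5, 40), 1),
             mean_framewise_displacement = round(runif(n, 0.05, 0.4), 3),
             updrs3_onoff = onoff,
             updrs3_onon = round(onoff * runif(n, 0.2, 0.9), 1),
             stringsAsFactors = FALSE)
}

make_cohort <- function(n = 6L, t_points = 40L, r = 6L, seed = 1L) {
  ids <- sprintf("s%02d", seq_len(n))
  ts_list <- lapply(seq_len(n), function(i) {
    make_ts(t_points, r, seed = seed + i, id = ids[i])
  })
  cohort(ts_list, make_phenotypes(ids, seed = seed))
}

random_adjacency <- function(r, p_edge = 0.35, seed = 1L) {
  set.seed(seed)
  a <- matrix(0L, r, r)
  a[upper.tri(a)] <- rbinom(r * (r - 1) / 2, 1L, p_edge)
  a + t(a)
}

# --- brute-force graph oracles (independent of igraph) -----------------

bf_distances <- function(a) {
  r <- nrow(a)
  d <- matrix(Inf, r, r)
  diag(d) <- 0
  for (s in seq_len(r)) {
    frontier <- s
    lev <- 0L
    while (length(frontier)) {
      lev <- lev + 1L
      nxt <- integer(0)
      for (v in frontier) {
        for (u in which(a[v, ] == 1L)) {
          if (d[s, u] > lev) {
            d[s, u] <- lev
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- unique(nxt)
    }
  }
  d
}

bf_global_efficiency <- function(a) {
  d <- bf_distances(a)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (nrow(a) * (nrow(a) - 1))
}

bf_assortativity <- function(a) {
  deg <- rowSums(a)
  e <- which(upper.tri(a) & a == 1, arr.ind = TRUE)
  if (!nrow(e)) return(NA_real_)
  x <- c(deg[e[, 1]], deg[e[, 2]])
  y <- c(deg[e[, 2]], deg[e[, 1]])
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

bf_clustering <- function(a) {
  r <- nrow(a)
  out <- numeric(r)
  for (i in seq_len(r)) {
    nb <- which(a[i, ] == 1L)
    k <- length(nb)
    if (k < 2L) next
    t_i <- 0L
    for (p in seq_len(k - 1L)) {
      for (q in (p + 1L):k) {
        t_i <- t_i + a[nb[p], nb[q]]
      }
    }
    out[i] <- 2 * t_i / (k * (k - 1))
  }
  out
}

# enumerate every shortest path between each pair and share them equally
bf_betweenness <- function(a) {
  r <- nrow(a)
  d <- bf_distances(a)
  btw <- numeric(r)
  enum_paths <- function(s, t) {
    # all shortest s->t paths by DFS constrained to the BFS level DAG
    paths <- list()
    walk <- function(v, path) {
      if (v == t) {
        paths[[length(paths) + 1L]] <<- path
        return(invisible())
      }
      for (u in which(a[v, ] == 1L)) {
        if (d[s, u] == d[s, v] + 1 && d[u, t] == d[v, t] - 1) {
          walk(u, c(path, u))
        }
      }
    }
    walk(s, integer(0))
    paths
  }
  for (s in seq_len(r - 1L)) {
    for (t in (s + 1L):r) {
      if (!is.finite(d[s, t])) next
      paths <- enum_paths(s, t)
      np <- length(paths)
      for (p in paths) {
        inner <- setdiff(p, t)
        if (length(inner)) btw[inner] <- btw[inner] + 1 / np
      }
    }
  }
  btw / ((r - 1) * (r - 2) / 2)
}
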