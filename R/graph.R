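#' Binarise a connectivity matrix at a proportional threshold
#'
#' Keeps the top \code{round(p/100 * R(R-1)/2)} upper-triangle edges by
#' signed weight (descending), ties broken by the fixed column-major
#' upper-triangle pair order, and returns the symmetric 0/1 adjacency.
#' Proportional (rather than absolute) thresholding fixes the density of
#' every graph in a cohort so that metric differences are not driven by
#' differences in gross connectivity level.
#'
#' @param m Connectivity matrix (square symmetric, diagonal ignored).
#' @param p Percentage of edges to keep, in (0, 100).
#' @param rank_by_absolute Rank edges by |weight| instead of signed
#'   weight (default \code{FALSE}).
#' @return R x R 0/1 matrix, zero diagonal, with attribute
#'   \code{density} = kept edges / possible edges.
#' @export
proportional_threshold <- function(m, p, rank_by_absolute = FALSE) {
  if (p <= 0 || p >= 100) stop("threshold percentage must be in (0, 100)")
  m <- as.matrix(m)
  r <- nrow(m)
  w <- m[upper.tri(m)]
  if (rank_by_absolute) w <- abs(w)
  e_max <- length(w)
  keep <- as.integer(floor(p / 100 * e_max + 0.5)) # round half up
  a <- matrix(0L, r, r)
  if (keep > 0L) {
    ord <- order(-w, seq_along(w)) # signed value desc, then fixed pair order
    sel <- ord[seq_len(min(keep, e_max))]
    ut <- which(upper.tri(m))
    a[ut[sel]] <- 1L
    a <- a + t(a)
  }
  dimnames(a) <- dimnames(m)
  attr(a, "density") <- keep / e_max
  a
}

.as_igraph <- function(a) {
  igraph::graph_from_adjacency_matrix(a != 0, mode = "undirected", diag = FALSE)
}

#' Global efficiency of a binary graph
#'
#' Mean over ordered node pairs of the inverse shortest-path length;
#' disconnected pairs contribute 0. Lies in [0, 1]; 1 for the complete
#' graph, 0 for the empty graph.
#'
#' @param a Symmetric 0/1 adjacency matrix.
#' @return Scalar in [0, 1].
#' @export
global_efficiency <- function(a) {
  a <- as.matrix(a)
  if (nrow(a) < 2L) stop("need at least 2 nodes")
  if (sum(a) == 0) return(0)
  d <- igraph::distances(.as_igraph(a))
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (nrow(a) * (nrow(a) - 1))
}

#' Degree assortativity of a binary graph
#'
#' Newman's degree-degree Pearson correlation over edge end points
#' (each undirected edge counted in both directions), computed directly
#' from the adjacency via the sum formulation
#' \deqn{r = \frac{M^{-1}\sum_e j_e k_e - [M^{-1}\sum_e (j_e+k_e)/2]^2}{
#'   M^{-1}\sum_e (j_e^2+k_e^2)/2 - [M^{-1}\sum_e (j_e+k_e)/2]^2}}
#' over the M undirected edges with end-point degrees j, k. Positive
#' values mean hubs attach to hubs, which is read as network
#' resilience. Returns \code{NA} (with a warning) when the end-point
#' degree variance is zero, e.g. on a regular graph.
#'
#' @param a Symmetric 0/1 adjacency matrix with at least one edge.
#' @return Scalar in [-1, 1], or \code{NA} when undefined.
#' @export
assortativity_degree_bin <- function(a) {
  a <- as.matrix(a)
  if (sum(a) == 0) stop("assortativity undefined for an edgeless graph")
  deg <- rowSums(a != 0)
  e <- which(upper.tri(a) & a != 0, arr.ind = TRUE)
  j <- deg[e[, 1L]]
  k <- deg[e[, 2L]]
  m <- length(j)
  mu <- sum(j + k) / (2 * m)
  num <- sum(j * k) / m - mu^2
  den <- sum(j^2 + k^2) / (2 * m) - mu^2
  if (den <= .Machine$double.eps * max(deg)^2) {
    warning("assortativity undefined (zero end-point degree variance)")
    return(NA_real_)
  }
  num / den
}

#' Per-node clustering coefficients of a binary graph
#'
#' C_i = 2 t_i / (k_i (k_i - 1)) where t_i counts triangles through node
#' i; nodes of degree < 2 get 0 by convention.
#'
#' @param a Symmetric 0/1 adjacency matrix.
#' @return Numeric vector (one value per node) in [0, 1].
#' @export
clustering_coefficients <- function(a) {
  a <- as.matrix(a)
  cc <- suppressWarnings(
    igraph::transitivity(.as_igraph(a), type = "local", isolates = "zero"))
  cc[is.nan(cc)] <- 0
  names(cc) <- colnames(a)
  cc
}

#' Normalised betweenness centrality of a binary graph
#'
#' Fraction-of-shortest-paths betweenness (equal splitting across tied
#' geodesics), normalised by (R-1)(R-2)/2 so values lie in [0, 1].
#'
#' @param a Symmetric 0/1 adjacency matrix, R >= 3.
#' @return Numeric vector per node.
#' @export
betweenness_centrality <- function(a) {
  a <- as.matrix(a)
  r <- nrow(a)
  if (r < 3L) stop("betweenness needs at least 3 nodes")
  b <- igraph::betweenness(.as_igraph(a), directed = FALSE)
  b <- b / ((r - 1) * (r - 2) / 2)
  names(b) <- colnames(a)
  b
}

.char_path_length <- function(g) {
  # mean finite geodesic on the largest connected component
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  sub <- igraph::induced_subgraph(g, keep)
  if (igraph::vcount(sub) < 2L) return(NA_real_)
  igraph::mean_distance(sub, directed = FALSE)
}

#' Small-worldness of a binary graph
#'
#' sigma = (C / C_null) / (L / L_null): mean clustering and
#' characteristic path length (largest component) relative to their
#' means over degree-preserving rewired null graphs. sigma > 1 is the
#' small-world regime. Returns \code{NA} with a warning when the null
#' ensemble degenerates (zero null clustering or impossible rewiring).
#'
#' @param a Symmetric 0/1 adjacency matrix.
#' @param n_null Number of rewired null graphs.
#' @param seed Integer seed for the rewiring.
#' @param rewire_per_edge Double-edge-swap attempts per edge per null.
#' @return Scalar, or \code{NA} when undefined.
#' @export
small_worldness <- function(a, n_null = 100L, seed = 1L,
                            rewire_per_edge = 10L) {
  a <- as.matrix(a)
  g <- .as_igraph(a)
  ne <- igraph::ecount(g)
  if (ne < 1L) stop("small-worldness undefined for an edgeless graph")
  c_obs <- mean(clustering_coefficients(a))
  l_obs <- .char_path_length(g)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  c_null <- l_null <- numeric(n_null)
  for (i in seq_len(n_null)) {
    gn <- igraph::rewire(g, igraph::keeping_degseq(niter = rewire_per_edge * ne))
    an <- igraph::as_adjacency_matrix(gn, sparse = FALSE)
    c_null[i] <- mean(clustering_coefficients(an))
    l_null[i] <- .char_path_length(gn)
  }
  cn <- mean(c_null)
  ln <- mean(l_null, na.rm = TRUE)
  if (!is.finite(cn) || cn <= 0 || !is.finite(ln) || ln <= 0 ||
      !is.finite(l_obs)) {
    warning("small-worldness undefined: degenerate null ensemble")
    return(NA_real_)
  }
  (c_obs / cn) / (l_obs / ln)
}

#' Area under a metric's threshold curve
#'
#' Trapezoidal integral of a per-threshold metric over the proportional
#' threshold grid expressed as a fraction (10% -> 0.10). Missing values
#' (e.g. undefined assortativity at some density) are excluded together
#' with their sub-intervals, with a warning.
#'
#' @param values Metric value per threshold (may contain \code{NA}).
#' @param thresholds Strictly increasing percentage grid.
#' @return Scalar AUC (\code{NA} if fewer than 2 defined points).
#' @export
metric_auc <- function(values, thresholds) {
  if (length(thresholds) < 2L) stop("need at least 2 thresholds for an AUC")
  if (length(values) != length(thresholds)) {
    stop("values and thresholds differ in length")
  }
  if (any(diff(thresholds) <= 0)) stop("thresholds must be strictly increasing")
  x <- thresholds / 100
  ok <- !is.na(values)
  if (any(!ok)) {
    warning(sum(!ok), " missing value(s) excluded from AUC")
  }
  seg <- which(ok[-length(ok)] & ok[-1L])
  if (!length(seg)) return(NA_real_)
  sum((x[seg + 1L] - x[seg]) * (values[seg] + values[seg + 1L]) / 2)
}

#' Graph-metric profile of one connectivity matrix
#'
#' Thresholds the matrix at every grid percentage, computes the global
#' metrics (global efficiency, assortativity, optionally
#' small-worldness) and the local metrics (clustering coefficient,
#' betweenness centrality) on each binary graph, and summarises every
#' metric by its AUC across the grid.
#'
#' @param m Connectivity matrix.
#' @param thresholds Percentage grid (default 10..34 by 1, i.e. 25
#'   graphs).
#' @param metrics Subset of
#'   \code{c("global_efficiency", "assortativity", "clustering",
#'   "betweenness", "small_worldness")}.
#' @param n_null,seed Passed to \code{\link{small_worldness}}.
#' @param rank_by_absolute Passed to
#'   \code{\link{proportional_threshold}}.
#' @return A \code{graph_profile} object: list with \code{thresholds},
#'   \code{global} (matrix metric x threshold), \code{local} (list of
#'   node x threshold matrices), \code{auc} (named list: scalars for
#'   global metrics, per-node vectors for local ones), \code{n_graphs}.
#' @export
profile_for_matrix <- function(m, thresholds = seq(10, 34, by = 1),
                               metrics = c("global_efficiency",
                                           "assortativity", "clustering",
                                           "betweenness",
                                           "small_worldness"),
                               n_null = 100L, seed = 1L,
                               rank_by_absolute = FALSE) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  m <- as.matrix(m)
  r <- nrow(m)
  labs <- colnames(m)
  nt <- length(thresholds)
  glob_names <- intersect(c("global_efficiency", "assortativity",
                            "small_worldness"), metrics)
  glob <- matrix(NA_real_, length(glob_names), nt,
                 dimnames = list(glob_names, thresholds))
  loc <- list()
  if ("clustering" %in% metrics) {
    loc$clustering <- matrix(NA_real_, r, nt, dimnames = list(labs, thresholds))
  }
  if ("betweenness" %in% metrics) {
    loc$betweenness <- matrix(NA_real_, r, nt, dimnames = list(labs, thresholds))
  }
  for (i in seq_len(nt)) {
    a <- proportional_threshold(m, thresholds[i],
                                rank_by_absolute = rank_by_absolute)
    if ("global_efficiency" %in% metrics) {
      glob["global_efficiency", i] <- global_efficiency(a)
    }
    if ("assortativity" %in% metrics) {
      glob["assortativity", i] <-
        if (sum(a) == 0) NA_real_ else
          suppressWarnings(assortativity_degree_bin(a))
    }
    if ("small_worldness" %in% metrics) {
      glob["small_worldness", i] <-
        if (sum(a) == 0) NA_real_ else
          suppressWarnings(small_worldness(a, n_null = n_null,
                                           seed = seed + i))
    }
    if ("clustering" %in% metrics) {
      loc$clustering[, i] <- clustering_coefficients(a)
    }
    if ("betweenness" %in% metrics) {
      loc$betweenness[, i] <- betweenness_centrality(a)
    }
  }
  auc <- list()
  for (gm in glob_names) {
    auc[[gm]] <- suppressWarnings(metric_auc(glob[gm, ], thresholds))
  }
  for (lm in names(loc)) {
    auc[[lm]] <- apply(loc[[lm]], 1L, function(v) {
      suppressWarnings(metric_auc(v, thresholds))
    })
  }
  structure(list(thresholds = thresholds, global = glob, local = loc,
                 auc = auc, n_graphs = nt),
            class = "graph_profile")
}

#' @export
print.graph_profile <- function(x, ...) {
  cat("Graph-metric profile over ", x$n_graphs, " thresholds (",
      min(x$thresholds), "-", max(x$thresholds), "%)\n", sep = "")
  for (gm in rownames(x$global)) {
    cat(sprintf("  %-18s AUC = %s\n", gm, format(x$auc[[gm]], digits = 4)))
  }
  invisible(x)
}
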