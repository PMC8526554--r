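#' Fisher-z edge features of windowed matrices
#'
#' @param matrices List of correlation-scale connectivity matrices.
#' @return Matrix, one row per window, columns = upper-triangle edges on
#'   the Fisher z scale.
#' @export
window_features <- function(matrices) {
  t(vapply(matrices, function(m) upper_tri_vec(fisher_z(m)),
           numeric(sum(upper.tri(matrices[[1L]])))))
}

.kmeans_best <- function(x, k, reps, iter_max = 50L) {
  best <- NULL
  r <- 0L
  attempts <- 0L
  while (r < reps && attempts < 10L * reps) {
    attempts <- attempts + 1L
    centers <- unique(x[sample.int(nrow(x), min(4L * k, nrow(x))), ,
                        drop = FALSE])
    if (nrow(centers) < k) next
    centers <- centers[seq_len(k), , drop = FALSE]
    km <- tryCatch(
      suppressWarnings(stats::kmeans(x, centers = centers,
                                     iter.max = iter_max,
                                     algorithm = "Lloyd")),
      error = function(e) NULL) # e.g. a cluster emptied out mid-run
    if (is.null(km)) next
    r <- r + 1L
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (is.null(best)) stop("k-means failed for k = ", k)
  best
}

#' Mean silhouette width of a clustering
#'
#' For each point, a = mean distance to its own cluster's other members,
#' b = smallest mean distance to another cluster; the silhouette is
#' (b - a) / max(a, b), with singleton clusters contributing 0. Returns
#' the mean over points. Euclidean distance.
#'
#' @param features Numeric matrix, one row per point (ignored when
#'   \code{dist_matrix} is given).
#' @param labels Integer cluster labels (>= 2 distinct values).
#' @param dist_matrix Optional precomputed full distance matrix, reused
#'   across candidate k to avoid recomputation.
#' @return Scalar in [-1, 1].
#' @export
silhouette_mean <- function(features, labels, dist_matrix = NULL) {
  labels <- as.integer(labels)
  ks <- sort(unique(labels))
  if (length(ks) < 2L) stop("silhouette needs at least 2 clusters")
  D <- if (is.null(dist_matrix)) .euclid_dist(as.matrix(features)) else dist_matrix
  n <- nrow(D)
  if (length(labels) != n) stop("labels do not match the number of points")
  Z <- outer(labels, ks, `==`) + 0 # n x k indicator
  counts <- colSums(Z)
  sums <- D %*% Z # total distance from each point to each cluster
  own <- match(labels, ks)
  a <- sums[cbind(seq_len(n), own)] / pmax(counts[own] - 1, 1)
  other <- sums / rep(counts, each = n)
  other[cbind(seq_len(n), own)] <- Inf
  b <- apply(other, 1L, min)
  s <- (b - a) / pmax(a, b)
  s[counts[own] == 1L] <- 0
  s[!is.finite(s)] <- 0
  mean(s)
}

.euclid_dist <- function(x) {
  g <- tcrossprod(x)
  dg <- diag(g)
  n <- length(dg)
  g <- -2 * g + dg           # adds dg_i (column-major recycling)
  g <- g + rep(dg, each = n) # adds dg_j
  sqrt(pmax(g, 0))
}

#' Spherical-Gaussian BIC of a k-means clustering
#'
#' BIC = n d ln(WSS / (n d)) + k (d + 1) ln(n), where WSS is the total
#' within-cluster squared Euclidean distance, n the number of points and
#' d the feature dimension. Lower is better; used to validate the
#' silhouette-selected cluster count.
#'
#' @param features Point matrix (n x d).
#' @param labels Integer labels.
#' @param centroids k x d centroid matrix.
#' @return Scalar BIC.
#' @export
bic_for_k <- function(features, labels, centroids) {
  x <- as.matrix(features)
  n <- nrow(x)
  d <- ncol(x)
  k <- nrow(centroids)
  wss <- sum((x - centroids[as.integer(labels), , drop = FALSE])^2)
  if (wss <= 0) stop("degenerate clustering: zero within-cluster dispersion")
  n * d * log(wss / (n * d)) + k * (d + 1) * log(n)
}

#' Cluster pooled windowed connectivity into brain states
#'
#' Pools every subject's windowed matrices, embeds them as Fisher-z edge
#' vectors, and for each candidate k runs k-means (\code{reps} random
#' restarts with random feature rows as initial centres, keeping the
#' lowest within-cluster dispersion). k is chosen by maximal mean
#' silhouette; the spherical-Gaussian BIC per k is reported alongside as
#' validation. States are relabelled in descending order of centroid
#' mean connectivity, so state 1 is always the most connected
#' (hyperconnected) state.
#'
#' @param subject_windows Named list (one entry per subject) of lists of
#'   windowed connectivity matrices.
#' @param k_range Candidate cluster counts (default 2..10).
#' @param reps Random restarts per k (default 100).
#' @param seed Integer seed.
#' @return A \code{state_decomposition}: list with \code{k},
#'   \code{centroids} (k x edges, Fisher z), \code{centroid_matrices}
#'   (correlation scale), \code{labels} (named list of per-subject
#'   per-window state indices), \code{silhouette_by_k}, \code{bic_by_k},
#'   \code{state_matrices} (per subject: list of per-state median
#'   matrices, \code{NULL} when unvisited), \code{region_labels}.
#' @export
cluster_states <- function(subject_windows, k_range = 2:10, reps = 100L,
                           seed = 1L) {
  stopifnot(length(subject_windows) >= 1L)
  mats <- unlist(subject_windows, recursive = FALSE)
  n_per_subj <- lengths(subject_windows)
  x <- window_features(mats)
  n <- nrow(x)
  k_max <- max(k_range)
  n_distinct <- nrow(unique(x))
  if (k_max >= n_distinct) {
    stop("k_max (", k_max, ") must be below the number of distinct windows (",
         n_distinct, ")")
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  D <- .euclid_dist(x)
  sil <- bic <- stats::setNames(numeric(length(k_range)), k_range)
  fits <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    km <- .kmeans_best(x, k_range[i], reps)
    fits[[i]] <- km
    sil[i] <- silhouette_mean(x, km$cluster, dist_matrix = D)
    bic[i] <- bic_for_k(x, km$cluster, km$centers)
  }
  pick <- which.max(sil)
  km <- fits[[pick]]
  k <- k_range[pick]
  # relabel: state 1 = highest centroid mean connectivity
  conn <- rowMeans(tanh(km$centers))
  ord <- order(conn, decreasing = TRUE)
  relabel <- match(km$cluster, ord)
  centroids <- km$centers[ord, , drop = FALSE]
  rownames(centroids) <- paste0("state", seq_len(k))
  labs_split <- split(relabel, rep(seq_along(n_per_subj), n_per_subj))
  names(labs_split) <- names(subject_windows)
  region_labels <- colnames(mats[[1L]])
  centroid_matrices <- lapply(seq_len(k), function(s) {
    vec_to_sym(tanh(centroids[s, ]), region_labels)
  })
  state_mats <- lapply(seq_along(subject_windows), function(i) {
    state_medians(subject_windows[[i]], labs_split[[i]], k)
  })
  names(state_mats) <- names(subject_windows)
  structure(list(k = k, centroids = centroids,
                 centroid_matrices = centroid_matrices,
                 labels = labs_split,
                 silhouette_by_k = sil, bic_by_k = bic,
                 state_matrices = state_mats,
                 region_labels = region_labels),
            class = "state_decomposition")
}

#' @export
print.state_decomposition <- function(x, ...) {
  cat("State decomposition: k = ", x$k, " (silhouette-selected from k = ",
      paste(range(as.integer(names(x$silhouette_by_k))), collapse = ".."),
      ")\n", sep = "")
  cat("  mean silhouette by k: ",
      paste(sprintf("%s:%.3f", names(x$silhouette_by_k), x$silhouette_by_k),
            collapse = "  "), "\n", sep = "")
  invisible(x)
}

#' Per-state median connectivity matrices of one subject
#'
#' Element-wise median over the subject's windows assigned to each
#' state; a state the subject never visits yields \code{NULL}.
#'
#' @param windows List of the subject's windowed matrices.
#' @param labels State index per window.
#' @param k Number of states.
#' @return List of length k (matrix or \code{NULL}).
#' @export
state_medians <- function(windows, labels, k = max(labels)) {
  stopifnot(length(windows) == length(labels))
  lapply(seq_len(k), function(s) {
    idx <- which(labels == s)
    if (!length(idx)) return(NULL)
    arr <- simplify2array(windows[idx])
    if (length(idx) == 1L) {
      m <- windows[[idx]]
    } else {
      m <- apply(arr, c(1L, 2L), stats::median)
    }
    dimnames(m) <- dimnames(windows[[1L]])
    m
  })
}

#' Temporal statistics of one subject's state label sequence
#'
#' Fraction of windows per state, mean dwell time per state in minutes
#' (mean maximal-run length x step x TR / 60) and the number of
#' transitions (adjacent label changes).
#'
#' @param labels State index per window (non-empty).
#' @param k Number of states.
#' @param tr_seconds TR in seconds.
#' @param step_tr Window step in TRs.
#' @return List with \code{fraction_time} (length k), \code{mean_dwell_min}
#'   (length k, \code{NA} for unvisited states), \code{n_transitions}.
#' @export
temporal_stats <- function(labels, k = max(labels), tr_seconds = 2.7,
                           step_tr = 1L) {
  if (!length(labels)) stop("empty label sequence")
  runs <- rle(as.integer(labels))
  frac <- dwell <- stats::setNames(numeric(k), paste0("state", seq_len(k)))
  dwell[] <- NA_real_
  for (s in seq_len(k)) {
    frac[s] <- mean(labels == s)
    lens <- runs$lengths[runs$values == s]
    if (length(lens)) {
      dwell[s] <- mean(lens) * step_tr * tr_seconds / 60
    }
  }
  list(fraction_time = frac, mean_dwell_min = dwell,
       n_transitions = length(runs$lengths) - 1L)
}
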