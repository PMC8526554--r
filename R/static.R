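#' Static functional connectivity of a subject
#'
#' Product-moment correlation between every pair of region time courses
#' over the full acquisition. The diagonal is set to 0 by convention: it
#' carries no connectivity information and is excluded from every
#' downstream summary.
#'
#' @param ts A \code{subject_ts} object or a T x R numeric matrix.
#' @return R x R symmetric correlation matrix, zero diagonal, with
#'   attribute \code{scale_tag = "r"}.
#' @export
static_fc <- function(ts) {
  x <- if (inherits(ts, "subject_ts")) ts$data else as.matrix(ts)
  if (nrow(x) < 3L) stop("need at least 3 time points for correlation")
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(x)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("zero-variance region(s): ", paste(bad, collapse = ", "))
  }
  r <- stats::cor(x)
  diag(r) <- 0
  r <- (r + t(r)) / 2
  attr(r, "scale_tag") <- "r"
  r
}

#' Fisher z transform of a connectivity matrix
#'
#' @param m Correlation-scale connectivity matrix.
#' @param clip Correlations are clipped to \code{[-clip, clip]} before
#'   \code{atanh} so near-unit edges stay finite.
#' @return Matrix of Fisher z values, zero diagonal,
#'   \code{scale_tag = "fisher_z"}.
#' @export
fisher_z <- function(m, clip = 1 - 1e-7) {
  z <- atanh(pmin(pmax(m, -clip), clip))
  diag(z) <- 0
  attr(z, "scale_tag") <- "fisher_z"
  z
}

#' Flatten the upper triangle of a square matrix into an edge vector
#' @param m Square matrix.
#' @return Numeric vector in fixed column-major upper-triangle order
#'   ((1,2), (1,3), (2,3), (1,4), ...).
#' @export
upper_tri_vec <- function(m) m[upper.tri(m)]

#' Rebuild a symmetric zero-diagonal matrix from an edge vector
#' @param v Edge vector in \code{\link{upper_tri_vec}} order.
#' @param labels Optional region labels.
#' @return Symmetric matrix with zero diagonal.
#' @export
vec_to_sym <- function(v, labels = NULL) {
  r <- (1 + sqrt(1 + 8 * length(v))) / 2
  if (abs(r - round(r)) > 1e-9) stop("edge vector length is not R(R-1)/2")
  r <- as.integer(round(r))
  m <- matrix(0, r, r)
  m[upper.tri(m)] <- v
  m <- m + t(m)
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  m
}

#' Residualise per-subject connectivity against cohort covariates
#'
#' Each edge's cross-subject vector is regressed (with intercept) on the
#' covariate design; the residuals plus the cohort mean replace the raw
#' values, and the group matrix is the mean of the adjusted matrices.
#' This is the transparent edge-wise analogue of incorporating age,
#' gender, disease severity and head motion as nuisance covariates when
#' forming the group connectivity representation.
#'
#' @param matrices Named list of per-subject connectivity matrices
#'   (identical dimensions).
#' @param covariates Numeric data.frame/matrix, one row per subject in the
#'   same order (no intercept column). May have zero columns, in which
#'   case the input is returned unchanged.
#' @return List with \code{adjusted} (named list of matrices) and
#'   \code{group_mean} (matrix).
#' @export
adjust_for_covariates <- function(matrices, covariates) {
  stopifnot(length(matrices) >= 2L)
  n <- length(matrices)
  Z <- as.matrix(covariates)
  if (nrow(Z) != n) stop("covariates must have one row per subject")
  E <- t(vapply(matrices, upper_tri_vec,
                numeric(length(upper_tri_vec(matrices[[1L]])))))
  if (ncol(Z) == 0L) {
    adj <- E
  } else {
    if (n < ncol(Z) + 2L) stop("need at least 2 more subjects than covariates")
    X <- cbind(1, Z)
    q <- qr(X)
    if (q$rank < ncol(X)) stop("rank-deficient covariate design")
    resid <- E - X %*% qr.coef(q, E)
    adj <- sweep(resid, 2L, colMeans(E), `+`)
  }
  labs <- colnames(matrices[[1L]])
  out <- lapply(seq_len(n), function(i) vec_to_sym(adj[i, ], labs))
  names(out) <- names(matrices)
  list(adjusted = out, group_mean = vec_to_sym(colMeans(adj), labs))
}

#' Overall functional connectivity of one matrix
#'
#' Mean of the strictly positive upper-triangle edge values; used
#' downstream as the control covariate that guards proportional
#' thresholding against between-subject differences in gross
#' connectivity level.
#'
#' @param m Connectivity matrix (correlation scale).
#' @return Positive scalar.
#' @export
overall_fc <- function(m) {
  v <- upper_tri_vec(m)
  pos <- v[v > 0]
  if (!length(pos)) {
    stop("no positive edge values; overall FC undefined for this subject")
  }
  mean(pos)
}

#' Cross-subject edge-wise variance of connectivity matrices
#'
#' Sample variance (n - 1 denominator) of every edge across subjects,
#' plus its mean over the upper triangle. Comparing this scalar between
#' the static matrices and each state's median matrices quantifies how
#' much between-subject spread the state decomposition absorbs.
#'
#' @param matrices List of >= 2 connectivity matrices of equal dimension.
#' @return List with \code{variance_matrix} and \code{mean_variance}.
#' @export
edgewise_variance <- function(matrices) {
  if (length(matrices) < 2L) stop("need at least 2 matrices")
  E <- t(vapply(matrices, upper_tri_vec,
                numeric(length(upper_tri_vec(matrices[[1L]])))))
  v <- apply(E, 2L, stats::var)
  list(variance_matrix = vec_to_sym(v, colnames(matrices[[1L]])),
       mean_variance = mean(v))
}
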