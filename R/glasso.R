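#' L1-penalised sparse inverse covariance (graphical lasso)
#'
#' Block coordinate-descent estimator of the penalised Gaussian
#' log-likelihood
#' \deqn{\log\det\Theta - \mathrm{tr}(S\Theta) - \lambda \|\Theta\|_1,}
#' cycling over columns of the working covariance and solving each
#' column's lasso subproblem by coordinate descent (compiled). The
#' penalty is applied to off-diagonal precision entries only (the
#' convention of the common toolbox implementations). Sized for the
#' small (tens of regions) matrices produced by windowed connectivity
#' estimation; the estimator is well defined even when the sample
#' covariance is rank deficient, as it is for short windows.
#'
#' @param s Symmetric sample covariance (or correlation) matrix.
#' @param lambda L1 penalty (> 0).
#' @param max_iter Maximum outer sweeps over all columns.
#' @param tol Convergence tolerance on the mean absolute change of the
#'   working covariance per sweep, relative to the mean absolute
#'   off-diagonal of \code{s}.
#' @return List with \code{cov} (estimated covariance, the inverse of
#'   the penalised precision), \code{precision}, \code{n_iter}.
#' @export
graphical_lasso <- function(s, lambda, max_iter = 200L, tol = 1e-6) {
  s <- as.matrix(s)
  p <- nrow(s)
  if (p != ncol(s) || max(abs(s - t(s))) > 1e-8) {
    stop("graphical_lasso needs a symmetric square matrix")
  }
  if (lambda <= 0) stop("lambda must be strictly positive")
  fit <- .glasso_cpp(s, lambda, as.integer(max_iter), tol)
  if (!fit$converged) {
    stop("graphical lasso did not converge in ", max_iter, " sweeps")
  }
  dimnames(fit$cov) <- dimnames(fit$precision) <- dimnames(s)
  fit[c("cov", "precision", "n_iter")]
}
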