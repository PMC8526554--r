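#' Number of sliding windows for a scan length
#'
#' Convention: \code{floor((T - W) / step)} windows, dropping the final
#' taper position whose trailing edge would touch the end of the scan.
#' With T = 253 time points, a 22-TR window and a 1-TR step this yields
#' 231 windows.
#'
#' @param t_points Number of time points T.
#' @param window_length_tr Window length W in TRs.
#' @param step_tr Step size in TRs.
#' @return Integer window count.
#' @export
n_windows <- function(t_points, window_length_tr, step_tr = 1L) {
  if (t_points <= window_length_tr) {
    stop("window length (", window_length_tr,
         ") must be smaller than the scan length (", t_points, ")")
  }
  if (step_tr < 1L) stop("step must be >= 1")
  as.integer(floor((t_points - window_length_tr) / step_tr))
}

#' Gaussian-tapered window weights
#'
#' A rectangle of length W convolved with a unit-mass Gaussian kernel of
#' standard deviation \code{sigma} TRs (kernel support +/- ceiling(3
#' sigma)); the central W samples are kept and renormalised to sum 1.
#' All weights are strictly positive and symmetric about the window
#' centre.
#'
#' @param window_length_tr Window length W.
#' @param sigma Gaussian standard deviation in TRs.
#' @return Numeric weight vector of length W summing to 1.
#' @export
taper_weights <- function(window_length_tr, sigma = 3) {
  if (sigma <= 0) stop("taper sigma must be positive")
  w <- as.integer(window_length_tr)
  if (w < 2L) stop("window length must be >= 2")
  half <- as.integer(ceiling(3 * sigma))
  kern <- stats::dnorm(seq(-half, half), sd = sigma)
  kern <- kern / sum(kern)
  # full discrete convolution of the unit rectangle with the kernel
  # (length w + 2*half); the central w samples are retained
  full <- numeric(w + 2L * half)
  for (j in seq_len(w)) {
    idx <- j:(j + 2L * half)
    full[idx] <- full[idx] + kern
  }
  centre <- full[(half + 1L):(half + w)]
  centre / sum(centre)
}

#' Taper-weighted covariance of one window
#'
#' Weighted covariance with the weighted mean removed per column;
#' weights are the normalised taper.
#'
#' @param x W x R matrix of the window's rows.
#' @param weights Taper weights summing to 1.
#' @return R x R covariance matrix.
#' @export
weighted_cov <- function(x, weights) {
  x <- as.matrix(x)
  w <- weights / sum(weights)
  mu <- colSums(x * w)
  xc <- sweep(x, 2L, mu)
  crossprod(xc * sqrt(w), xc * sqrt(w))
}

.to_corr <- function(s) {
  d <- sqrt(diag(s))
  if (any(d <= 0)) stop("zero-variance region inside a window")
  r <- s / tcrossprod(d)
  diag(r) <- 1
  (r + t(r)) / 2
}

#' Sliding-window functional connectivity
#'
#' For each window the taper-weighted covariance is formed, standardised
#' to correlation, and (for \code{lambda > 0}) the sparse inverse
#' covariance is estimated by graphical lasso; the regularised precision
#' is inverted back and reported on the correlation scale with zero
#' diagonal. \code{lambda = 0} reduces exactly to the unpenalised
#' tapered correlation.
#'
#' @param ts \code{subject_ts} or T x R matrix.
#' @param window_length_tr,sigma,step_tr Window specification (see
#'   \code{\link{taper_weights}}).
#' @param lambda L1 penalty for the graphical lasso (>= 0).
#' @return A \code{windowed_fc} object: list with \code{matrices} (list of
#'   R x R correlation matrices, zero diagonal), \code{window_starts}
#'   (1-based first row of each window), \code{lambda_used},
#'   \code{taper}.
#' @export
windowed_fc <- function(ts, window_length_tr = 22L, sigma = 3, step_tr = 1L,
                        lambda = 0) {
  x <- if (inherits(ts, "subject_ts")) ts$data else as.matrix(ts)
  if (lambda < 0) stop("lambda must be non-negative")
  nw <- n_windows(nrow(x), window_length_tr, step_tr)
  wts <- taper_weights(window_length_tr, sigma)
  starts <- 1L + (seq_len(nw) - 1L) * as.integer(step_tr)
  labs <- colnames(x)
  mats <- vector("list", nw)
  for (i in seq_len(nw)) {
    rows <- starts[i]:(starts[i] + window_length_tr - 1L)
    s <- .to_corr(weighted_cov(x[rows, , drop = FALSE], wts))
    if (lambda > 0) {
      fit <- tryCatch(graphical_lasso(s, lambda),
                      error = function(e) {
                        stop("graphical lasso failed at window ", i, ": ",
                             conditionMessage(e))
                      })
      s <- .to_corr(fit$cov)
    }
    diag(s) <- 0
    dimnames(s) <- list(labs, labs)
    attr(s, "scale_tag") <- "r"
    mats[[i]] <- s
  }
  structure(list(matrices = mats, window_starts = starts,
                 lambda_used = lambda, taper = wts),
            class = "windowed_fc")
}

#' @export
print.windowed_fc <- function(x, ...) {
  cat("Windowed FC: ", length(x$matrices), " windows, lambda = ",
      x$lambda_used, "\n", sep = "")
  invisible(x)
}

#' Raw tapered window correlation matrices (no regularisation)
#'
#' Convenience wrapper used by \code{\link{select_lambda}}: the
#' unpenalised per-window tapered correlation matrices with unit
#' diagonal.
#'
#' @inheritParams windowed_fc
#' @return List of R x R correlation matrices (unit diagonal).
#' @export
window_covariances <- function(ts, window_length_tr = 22L, sigma = 3,
                               step_tr = 1L) {
  x <- if (inherits(ts, "subject_ts")) ts$data else as.matrix(ts)
  nw <- n_windows(nrow(x), window_length_tr, step_tr)
  wts <- taper_weights(window_length_tr, sigma)
  starts <- 1L + (seq_len(nw) - 1L) * as.integer(step_tr)
  lapply(seq_len(nw), function(i) {
    rows <- starts[i]:(starts[i] + window_length_tr - 1L)
    .to_corr(weighted_cov(x[rows, , drop = FALSE], wts))
  })
}

#' Select the graphical-lasso penalty for one subject
#'
#' Repeated random train/test splits of the subject's windows: for each
#' repetition the penalised precision is fitted to the pooled training
#' covariance at every grid value and scored by the average Gaussian
#' log-likelihood \code{log det(Theta) - tr(S_test Theta)} over the test
#' windows. The lambda with the best mean held-out score across
#' repetitions is returned.
#'
#' @param window_covs List of per-window covariance/correlation matrices
#'   (e.g. from \code{\link{window_covariances}}).
#' @param grid Candidate lambda values (non-empty, non-negative).
#' @param n_reps Number of train/test repetitions.
#' @param seed Integer seed making the splits reproducible.
#' @return List with \code{lambda} (selected value) and \code{scores}
#'   (grid x reps matrix of held-out log-likelihoods).
#' @export
select_lambda <- function(window_covs, grid, n_reps = 10L, seed = 1L) {
  if (!length(grid)) stop("lambda grid is empty")
  if (any(grid < 0)) stop("lambda values must be non-negative")
  nw <- length(window_covs)
  if (nw < 4L) stop("need at least 4 windows to split")
  if (length(grid) == 1L) {
    return(list(lambda = grid[[1L]],
                scores = matrix(NA_real_, 1L, 0L,
                                dimnames = list(as.character(grid), NULL))))
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  scores <- matrix(NA_real_, length(grid), n_reps)
  rownames(scores) <- as.character(grid)
  for (rep in seq_len(n_reps)) {
    train_idx <- sample.int(nw, floor(nw / 2))
    s_train <- Reduce(`+`, window_covs[train_idx]) / length(train_idx)
    test <- window_covs[-train_idx]
    for (g in seq_along(grid)) {
      theta <- if (grid[g] == 0) {
        solve(s_train + diag(1e-8, nrow(s_train)))
      } else {
        graphical_lasso(s_train, grid[g])$precision
      }
      ld <- determinant(theta, logarithm = TRUE)$modulus
      ll <- vapply(test, function(s) as.numeric(ld) - sum(s * theta), 0)
      scores[g, rep] <- mean(ll)
    }
  }
  list(lambda = grid[[which.max(rowMeans(scores))]], scores = scores)
}
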