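#' Default 25-region, 8-network layout of the synthetic cohort
#'
#' Region counts per network follow the study system being emulated:
#' salience (Sa) 1, default mode (DMN) 7, frontoparietal (FPN) 7,
#' sensorimotor (SM) 4, cerebellar (Ce) 2, visual (Vi) 2, auditory (Au)
#' 1, language (La) 1.
#'
#' @return Data.frame with \code{region} and \code{network}.
#' @export
default_network_layout <- function() {
  counts <- c(Sa = 1L, DMN = 7L, FPN = 7L, SM = 4L, Ce = 2L, Vi = 2L,
              Au = 1L, La = 1L)
  network <- rep(names(counts), counts)
  data.frame(region = sprintf("%s%02d", network,
                              unlist(lapply(counts, seq_len))),
             network = network, stringsAsFactors = FALSE)
}

.nearest_corr <- function(m, eps = 1e-4) {
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  vals <- pmax(e$values, eps)
  m2 <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(m2))
  r <- m2 / tcrossprod(d)
  diag(r) <- 1
  (r + t(r)) / 2
}

#' Correlation templates of the two planted connectivity states
#'
#' State 1 is hyperconnected: strong within-network blocks and moderate
#' between-network coupling everywhere. State 2 is hypoconnected:
#' coupling survives mainly inside the SM, DMN and Vi blocks. Both are
#' projected to valid (positive definite) correlation matrices.
#'
#' @param layout Network layout data.frame (see
#'   \code{\link{default_network_layout}}).
#' @return List with \code{state1} and \code{state2} correlation
#'   matrices and the \code{layout}.
#' @export
state_templates <- function(layout = default_network_layout()) {
  nw <- layout$network
  r <- nrow(layout)
  same <- outer(nw, nw, `==`)
  s1 <- matrix(0.30, r, r)
  s1[same] <- 0.60
  s2 <- matrix(0.05, r, r)
  s2[same] <- 0.15
  strong <- nw %in% c("SM", "DMN", "Vi")
  s2[same & outer(strong, strong, `&`)] <- 0.45
  diag(s1) <- diag(s2) <- 1
  s1 <- .nearest_corr(s1)
  s2 <- .nearest_corr(s2)
  dimnames(s1) <- dimnames(s2) <- list(layout$region, layout$region)
  list(state1 = s1, state2 = s2, layout = layout)
}

#' Realise a planted Markov state sequence
#'
#' First-order two-or-more-state Markov chain with per-state stay
#' probabilities; on leaving a state the chain moves uniformly to one of
#' the others. The initial state is drawn from the stationary
#' distribution (closed form for two states, uniform otherwise).
#'
#' @param t_points Sequence length T.
#' @param stay_probs Per-state stay probabilities in (0, 1].
#' @param seed Integer seed.
#' @return Integer vector of state indices in 1..length(stay_probs).
#' @export
planted_state_sequence <- function(t_points, stay_probs, seed = 1L) {
  if (t_points < 1L) stop("t_points must be >= 1")
  if (any(stay_probs < 0) || any(stay_probs > 1)) {
    stop("stay probabilities must lie in [0, 1]")
  }
  k <- length(stay_probs)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  leave <- 1 - stay_probs
  pi0 <- if (k == 2L) {
    if (sum(leave) == 0) c(0.5, 0.5) else rev(leave) / sum(leave)
  } else rep(1 / k, k)
  s <- integer(t_points)
  s[1L] <- sample.int(k, 1L, prob = pi0)
  if (t_points > 1L) {
    u <- stats::runif(t_points - 1L)
    jump <- stats::runif(t_points - 1L)
    for (t in 2:t_points) {
      cur <- s[t - 1L]
      if (u[t - 1L] <= stay_probs[cur]) {
        s[t] <- cur
      } else {
        others <- seq_len(k)[-cur]
        s[t] <- others[ceiling(jump[t - 1L] * (k - 1L))]
      }
    }
  }
  s
}

#' Simulate one subject's region time series
#'
#' At each time point a zero-mean Gaussian draw from the active state's
#' covariance is taken; AR(1) temporal smoothing with coefficient
#' \code{ar_coef} (variance-preserving form) is then applied and columns
#' are restandardised. This switches covariance structure pointwise
#' rather than modelling a hemodynamic response -- a deliberate
#' simulation simplification sufficient to stress windowed estimation.
#'
#' @param state_sequence Integer state index per time point.
#' @param state_covs List of R x R positive-definite covariance
#'   matrices, one per state.
#' @param tr_seconds TR in seconds.
#' @param ar_coef AR(1) coefficient in [0, 1).
#' @param subject_id Subject identifier.
#' @param seed Integer seed.
#' @param network_labels Optional per-region network labels.
#' @return A \code{subject_ts}.
#' @export
generate_subject <- function(state_sequence, state_covs, tr_seconds = 2.7,
                             ar_coef = 0.3, subject_id = "sim01", seed = 1L,
                             network_labels = NULL) {
  k <- length(state_covs)
  stopifnot(all(state_sequence %in% seq_len(k)))
  r <- nrow(state_covs[[1L]])
  chols <- lapply(state_covs, function(s) {
    ch <- tryCatch(chol(s), error = function(e) {
      stop("state covariance is not positive definite")
    })
    ch
  })
  t_points <- length(state_sequence)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  z <- matrix(stats::rnorm(t_points * r), t_points, r)
  eps <- matrix(0, t_points, r)
  for (s in seq_len(k)) {
    rows <- which(state_sequence == s)
    if (length(rows)) {
      eps[rows, ] <- z[rows, , drop = FALSE] %*% chols[[s]]
    }
  }
  x <- eps
  if (ar_coef != 0) {
    if (abs(ar_coef) >= 1) stop("ar_coef must satisfy |ar_coef| < 1")
    sc <- sqrt(1 - ar_coef^2)
    for (t in 2:t_points) {
      x[t, ] <- ar_coef * x[t - 1L, ] + sc * eps[t, ]
    }
  }
  x <- scale(x)
  attr(x, "scaled:center") <- attr(x, "scaled:scale") <- NULL
  colnames(x) <- colnames(state_covs[[1L]])
  subject_ts(x, tr_seconds, subject_id = subject_id,
             network_labels = network_labels)
}

.resilience_direction <- function(template, layout) {
  # hubs = regions of the strong state-2 blocks (SM, DMN, Vi); positive
  # resilience moves edge weight from hub-leaf pairs onto hub-hub pairs
  hub <- layout$network %in% c("SM", "DMN", "Vi")
  d <- matrix(0, nrow(template), ncol(template))
  d[hub, hub] <- 1
  d[hub, !hub] <- -0.35
  d[!hub, hub] <- -0.35
  diag(d) <- 0
  d
}

#' State-2 covariance of a subject at a given resilience
#'
#' Adds \code{resilience * delta} times the hub-rewiring direction to
#' the hypoconnected template and projects back to a correlation
#' matrix. Higher resilience strengthens hub-hub edges at the expense of
#' hub-leaf edges, raising the assortativity of the thresholded graphs.
#'
#' @param resilience Scalar, typically in [-1, 1].
#' @param templates Output of \code{\link{state_templates}}.
#' @param delta Perturbation scale.
#' @return Correlation matrix.
#' @export
state2_for_resilience <- function(resilience, templates = state_templates(),
                                  delta = 0.12) {
  d <- .resilience_direction(templates$state2, templates$layout)
  m <- .nearest_corr(templates$state2 + resilience * delta * d)
  dimnames(m) <- dimnames(templates$state2)
  m
}

#' Generate a synthetic cohort with known ground truth
#'
#' Emulates the study conditions: \code{t_points = 253} volumes at TR =
#' 2.7 s over 25 regions in 8 networks, two latent connectivity states
#' with Markov dwell structure (stay probabilities chosen so the
#' hypoconnected state 2 occupies about two thirds of the scan with
#' roughly 4 transitions), and a planted correlation between each
#' subject's true hypoconnected-state assortativity AUC and the DBS
#' response percentage. Phenotype covariates are drawn with the cohort
#' dispersion of the emulated study.
#'
#' @param n_subjects Number of subjects (>= 4).
#' @param t_points Time points per subject.
#' @param tr_seconds TR in seconds.
#' @param stay_probs Per-state Markov stay probabilities shared by all
#'   subjects. The default \code{NULL} draws a per-subject target
#'   occupancy u_i of the hypoconnected state from a Beta distribution
#'   (mean ~2/3, sd ~0.3, matching the emulated cohort's occupancy
#'   spread) and sets the subject's leave rates to
#'   \code{switch_rate * c(u_i, 1 - u_i)}, which fixes the expected
#'   occupancy at u_i while keeping the expected number of transitions
#'   at roughly 4 per scan.
#' @param switch_rate Total Markov switching intensity used when
#'   \code{stay_probs} is \code{NULL}.
#' @param planted_r Target correlation between true state-2
#'   assortativity AUC and response, in (-1, 1).
#' @param resilience_sd Spread of the latent resilience draw (truncated
#'   at +/- 2 sd, then scaled into [-1, 1]).
#' @param ar_coef AR(1) smoothing coefficient.
#' @param thresholds Threshold grid used for the true assortativity AUC.
#' @param simulate_timeseries If \code{FALSE}, skip sampling the time
#'   series (ground truth and phenotypes only; used by large simulation
#'   studies that operate on the true matrices).
#' @param seed Integer seed; the whole cohort is a deterministic
#'   function of it.
#' @return A \code{dfc_cohort} (when \code{simulate_timeseries}) with an
#'   extra \code{truth} element, otherwise a list with \code{phenotypes}
#'   and \code{truth}. \code{truth} holds per-subject state sequences,
#'   state covariances, resilience, true state-2 assortativity AUC,
#'   occupancy, response, and the templates and seed.
#' @export
generate_cohort <- function(n_subjects = 18L, t_points = 253L,
                            tr_seconds = 2.7,
                            stay_probs = NULL, switch_rate = 0.06,
                            planted_r = -0.7, resilience_sd = 0.5,
                            ar_coef = 0.3,
                            thresholds = seq(10, 34, by = 1),
                            simulate_timeseries = TRUE, seed = 1L) {
  if (n_subjects < 4L) stop("need at least 4 subjects")
  if (abs(planted_r) >= 1) stop("planted correlation must lie in (-1, 1)")
  tmpl <- state_templates()
  layout <- tmpl$layout
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(stage_seed(seed, "cohort"))
  ids <- sprintf("sim%03d", seq_len(n_subjects))
  resilience <- pmin(pmax(stats::rnorm(n_subjects, 0, resilience_sd), -1), 1)
  state2 <- lapply(resilience, state2_for_resilience, templates = tmpl)
  # true hypoconnected-state assortativity AUC per subject
  a_true <- vapply(state2, function(m) {
    mm <- m
    diag(mm) <- 0
    profile_for_matrix(mm, thresholds, metrics = "assortativity")$auc$assortativity
  }, 0)
  az <- if (stats::sd(a_true) > 0) as.numeric(scale(a_true)) else
    rep(0, n_subjects)
  noise <- stats::rnorm(n_subjects)
  resp_z <- planted_r * az + sqrt(1 - planted_r^2) * noise
  response <- pmin(pmax(53.5 + 16.7 * resp_z, 0), 100)
  if (is.null(stay_probs)) {
    # Beta(0.98, 0.48): mean ~0.67, sd ~0.30 hypoconnected-state occupancy
    u <- pmin(pmax(stats::rbeta(n_subjects, 0.98, 0.48), 0.05), 0.95)
    subj_stay <- lapply(u, function(ui) {
      pmax(1 - switch_rate * c(ui, 1 - ui), 0)
    })
  } else {
    subj_stay <- rep(list(stay_probs), n_subjects)
  }
  sequences <- lapply(seq_len(n_subjects), function(i) {
    planted_state_sequence(t_points, subj_stay[[i]],
                           seed = stage_seed(seed, paste0("seq", i)))
  })
  occupancy <- t(vapply(sequences, function(s) {
    c(mean(s == 1L), mean(s == 2L))
  }, numeric(2)))
  colnames(occupancy) <- c("state1", "state2")
  age <- round(pmin(pmax(stats::rnorm(n_subjects, 55.3, 10.1), 40), 75), 1)
  gender <- stats::rbinom(n_subjects, 1L, 4 / 18)
  updrs_on <- round(pmin(pmax(stats::rnorm(n_subjects, 17.4, 10.1), 4), 42), 1)
  fd <- round(exp(stats::rnorm(n_subjects, log(0.2), 0.4)), 4)
  onoff <- round(pmax(stats::rnorm(n_subjects, 27.1, 16.8), 2), 1)
  onon <- round(onoff * (1 - response / 100), 2)
  phen <- data.frame(subject_id = ids, age_years = age, gender = gender,
                     updrs3_on_preop = updrs_on,
                     mean_framewise_displacement = fd,
                     updrs3_onoff = onoff, updrs3_onon = onon,
                     stringsAsFactors = FALSE)
  truth <- list(state_sequences = stats::setNames(sequences, ids),
                state1_cov = tmpl$state1, state2_cov = stats::setNames(state2, ids),
                resilience = stats::setNames(resilience, ids),
                true_assortativity_auc = stats::setNames(a_true, ids),
                occupancy = occupancy,
                response = stats::setNames(response, ids),
                stay_probs = subj_stay, planted_r = planted_r,
                layout = layout, seed = seed)
  if (!simulate_timeseries) {
    return(list(phenotypes = phen, truth = truth))
  }
  ts_list <- lapply(seq_len(n_subjects), function(i) {
    generate_subject(sequences[[i]],
                     list(tmpl$state1, state2[[i]]),
                     tr_seconds = tr_seconds, ar_coef = ar_coef,
                     subject_id = ids[i],
                     seed = stage_seed(seed, paste0("subj", i)),
                     network_labels = layout$network)
  })
  ch <- cohort(ts_list, phen)
  ch$truth <- truth
  ch
}

#' Majority-vote window labels implied by a per-TR state sequence
#'
#' Converts a generator state sequence (one state per time point) into
#' ground-truth labels at window resolution: each window takes the state
#' occupying most of its span (ties go to the earlier-visited state).
#'
#' @param state_sequence Integer state per time point.
#' @param window_length_tr,step_tr Window specification.
#' @return Integer label per window.
#' @export
true_window_labels <- function(state_sequence, window_length_tr = 22L,
                               step_tr = 1L) {
  nw <- n_windows(length(state_sequence), window_length_tr, step_tr)
  starts <- 1L + (seq_len(nw) - 1L) * as.integer(step_tr)
  vapply(starts, function(s) {
    span <- state_sequence[s:(s + window_length_tr - 1L)]
    tab <- table(span)
    as.integer(names(tab)[which.max(tab)])
  }, 0L)
}
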