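#' Multi-seed brain-state recovery experiment
#'
#' Repeatedly generates a default synthetic cohort (two well-separated
#' planted states with Markov dwell structure), runs the windowed-FC +
#' pooled k-means decomposition, and scores recovery against the
#' generator's ground truth: whether silhouette selects k = 2, the
#' window-label accuracy (best over the label permutation), and the
#' correlation between estimated and true per-subject state-2 fraction
#' times. Windows use the unpenalised tapered correlation
#' (\code{lambda = 0}); the clustering settings are scaled for a
#' repeated experiment (see the methods vignette).
#'
#' @param n_seeds Number of generator seeds.
#' @param n_subjects Subjects per cohort.
#' @param t_points Time points per subject.
#' @param window_length_tr,taper_sigma_tr,step_tr Window specification.
#' @param k_range Candidate cluster counts.
#' @param reps k-means restarts per k.
#' @param seed Master seed; per-iteration seeds are derived from it.
#' @return Data.frame with one row per seed: \code{k_selected},
#'   \code{accuracy}, \code{fraction_time_cor}.
#' @export
state_recovery_experiment <- function(n_seeds = 20L, n_subjects = 18L,
                                      t_points = 253L,
                                      window_length_tr = 22L,
                                      taper_sigma_tr = 3, step_tr = 1L,
                                      k_range = 2:5, reps = 8L, seed = 1L) {
  out <- data.frame(seed = seq_len(n_seeds), k_selected = NA_integer_,
                    accuracy = NA_real_, fraction_time_cor = NA_real_)
  for (i in seq_len(n_seeds)) {
    s <- stage_seed(seed, paste0("recovery", i))
    ch <- generate_cohort(n_subjects = n_subjects, t_points = t_points,
                          seed = s)
    wl <- lapply(ch$ts, function(ts) {
      windowed_fc(ts, window_length_tr, taper_sigma_tr, step_tr,
                  lambda = 0)$matrices
    })
    dec <- cluster_states(wl, k_range = k_range, reps = reps,
                          seed = stage_seed(s, "cluster"))
    out$k_selected[i] <- dec$k
    truth <- lapply(ch$truth$state_sequences, true_window_labels,
                    window_length_tr = window_length_tr, step_tr = step_tr)
    est <- unlist(dec$labels)
    tru <- unlist(truth)
    if (dec$k == 2L) {
      out$accuracy[i] <- max(mean(est == tru), mean((3L - est) == tru))
      ft_est <- vapply(dec$labels, function(l) mean(l == 2L), 0)
      ft_tru <- vapply(truth, function(l) mean(l == 2L), 0)
      out$fraction_time_cor[i] <-
        if (stats::sd(ft_est) > 0 && stats::sd(ft_tru) > 0) {
          stats::cor(ft_est, ft_tru)
        } else NA_real_
    }
    rm(dec, wl, ch)
    gc(FALSE)
  }
  out
}

#' Multi-seed planted-association recovery experiment
#'
#' For each generator seed, draws a cohort with a planted correlation
#' between the true hypoconnected-state (state 2) assortativity AUC and
#' the DBS response, then runs the association test exactly as the
#' pipeline does: Pearson partial correlation of the state-2
#' assortativity AUC with response, controlling for the subject's
#' overall functional connectivity. The state-2 matrices used are the
#' generator's true per-subject matrices, isolating the statistical
#' recovery of the planted effect from windowed-estimation noise.
#'
#' @param n_seeds Number of generator seeds.
#' @param n_subjects Subjects per cohort.
#' @param planted_r Planted correlation (e.g. -0.7, or 0 for a null
#'   calibration run).
#' @param thresholds Proportional-threshold grid for the AUC.
#' @param seed Master seed.
#' @return Data.frame with one row per seed: \code{r} (partial
#'   correlation) and \code{p}.
#' @export
association_recovery_experiment <- function(n_seeds = 100L, n_subjects = 60L,
                                            planted_r = -0.7,
                                            thresholds = seq(10, 34, by = 1),
                                            seed = 1L) {
  out <- data.frame(seed = seq_len(n_seeds), r = NA_real_, p = NA_real_)
  for (i in seq_len(n_seeds)) {
    s <- stage_seed(seed, paste0("assoc", i))
    ch <- generate_cohort(n_subjects = n_subjects, planted_r = planted_r,
                          thresholds = thresholds,
                          simulate_timeseries = FALSE, seed = s)
    truth <- ch$truth
    response <- dbs_response(ch$phenotypes$updrs3_onoff,
                             ch$phenotypes$updrs3_onon)
    auc <- truth$true_assortativity_auc
    # overall FC from each subject's expected (occupancy-weighted) matrix
    ofc <- vapply(seq_len(n_subjects), function(j) {
      m <- truth$occupancy[j, 1L] * truth$state1_cov +
        truth$occupancy[j, 2L] * truth$state2_cov[[j]]
      diag(m) <- 0
      overall_fc(m)
    }, 0)
    pc <- partial_correlation(auc, response, ofc)
    out$r[i] <- pc$r
    out$p[i] <- pc$p
  }
  out
}
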