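#' Fit the full dynamic-connectivity brain-state analysis to a cohort
#'
#' The one-call interface: runs every stage of the pipeline on an
#' in-memory cohort and returns a classed result. Stages, in order:
#' \enumerate{
#'   \item Static FC per subject; edge-wise residualisation against the
#'     phenotype covariates (age, gender, preoperative UPDRS-III ON,
#'     mean framewise displacement); overall-FC scalar per subject;
#'     cross-subject edge variance.
#'   \item Sliding-window tapered FC per subject, with a per-subject
#'     graphical-lasso penalty selected by held-out likelihood over the
#'     configured grid.
#'   \item Pooled k-means decomposition into brain states (silhouette
#'     selection of k, BIC validation), per-subject per-state median
#'     matrices and temporal statistics.
#'   \item Graph-metric profiles (proportional-threshold sweep + AUC)
#'     for the static matrices and every state median matrix.
#'   \item Covariate-controlled partial correlations of metric AUCs, FC
#'     edges and temporal statistics with the DBS response, with FDR
#'     control within the local-metric and edge families.
#' }
#'
#' @param ch A \code{dfc_cohort} (see \code{\link{cohort}},
#'   \code{\link{read_cohort}}, \code{\link{generate_cohort}}).
#' @param config A \code{\link{run_config}}.
#' @return A \code{dfc_study} object; see the methods
#'   \code{print}, \code{summary} and \code{plot}.
#' @export
dfc_study <- function(ch, config = run_config()) {
  stopifnot(inherits(ch, "dfc_cohort"))
  t0 <- Sys.time()
  warnings_log <- character()
  note <- function(msg) warnings_log <<- c(warnings_log, msg)
  ids <- names(ch$ts)
  phen <- ch$phenotypes
  response <- stats::setNames(dbs_response(phen$updrs3_onoff,
                                           phen$updrs3_onon),
                              phen$subject_id)

  ## stage 1: static connectivity ------------------------------------
  static_raw <- lapply(ch$ts, static_fc)
  covs <- phen[, c("age_years", "gender", "updrs3_on_preop",
                   "mean_framewise_displacement")]
  const <- vapply(covs, function(v) stats::sd(v) == 0, TRUE)
  if (any(const)) {
    note(paste0("constant covariate(s) dropped from adjustment: ",
                paste(names(covs)[const], collapse = ", ")))
    covs <- covs[, !const, drop = FALSE]
  }
  adj <- adjust_for_covariates(static_raw, covs)
  ofc <- vapply(static_raw, overall_fc, 0)
  static_var <- edgewise_variance(adj$adjusted)

  ## stage 2: windowed connectivity ----------------------------------
  w <- config$window_length_tr
  sig <- config$taper_sigma_tr
  step <- config$step_tr
  lam_seed <- stage_seed(config$rng_seed, "lambda")
  windows <- list()
  lambda_by_subject <- stats::setNames(numeric(length(ids)), ids)
  for (i in seq_along(ids)) {
    id <- ids[i]
    raw <- window_covariances(ch$ts[[id]], w, sig, step)
    lam <- if (length(config$lambda_grid) > 1L) {
      select_lambda(raw, config$lambda_grid, config$lambda_reps,
                    seed = lam_seed + i)$lambda
    } else config$lambda_grid[[1L]]
    lambda_by_subject[id] <- lam
    windows[[id]] <- windowed_fc(ch$ts[[id]], w, sig, step, lambda = lam)
  }

  ## stage 3: brain states -------------------------------------------
  decomp <- cluster_states(lapply(windows, `[[`, "matrices"),
                           k_range = config$k_min:config$k_max,
                           reps = config$kmeans_reps,
                           seed = stage_seed(config$rng_seed, "states"))
  temporal <- lapply(decomp$labels, temporal_stats, k = decomp$k,
                     tr_seconds = ch$tr_seconds, step_tr = step)
  names(temporal) <- ids

  ## per-state covariate adjustment and variance ----------------------
  state_mats_adj <- vector("list", decomp$k)
  state_var <- stats::setNames(rep(NA_real_, decomp$k),
                               paste0("state", seq_len(decomp$k)))
  for (s in seq_len(decomp$k)) {
    have <- ids[vapply(ids, function(id) {
      !is.null(decomp$state_matrices[[id]][[s]])
    }, TRUE)]
    miss <- setdiff(ids, have)
    if (length(miss)) {
      note(paste0("state ", s, ": ", length(miss),
                  " subject(s) never visit it (", paste(miss, collapse = ", "),
                  "); excluded pairwise"))
    }
    mats <- lapply(have, function(id) decomp$state_matrices[[id]][[s]])
    names(mats) <- have
    if (length(have) > ncol(covs) + 2L) {
      adj_s <- adjust_for_covariates(mats, covs[match(have, ids), ,
                                                drop = FALSE])$adjusted
    } else {
      adj_s <- mats
    }
    state_mats_adj[[s]] <- adj_s
    if (length(adj_s) >= 2L) {
      state_var[s] <- edgewise_variance(adj_s)$mean_variance
    }
  }

  ## stage 4: graph profiles -----------------------------------------
  thr <- threshold_grid(config)
  gseed <- stage_seed(config$rng_seed, "graph")
  prof_static <- lapply(adj$adjusted, profile_for_matrix, thresholds = thr,
                        n_null = config$n_null_graphs, seed = gseed,
                        rank_by_absolute = config$rank_by_absolute)
  profiles <- list(static = prof_static)
  fc_conditions <- list(static = adj$adjusted)
  for (s in seq_len(decomp$k)) {
    profiles[[paste0("state", s)]] <-
      lapply(state_mats_adj[[s]], profile_for_matrix, thresholds = thr,
             n_null = config$n_null_graphs, seed = gseed,
             rank_by_absolute = config$rank_by_absolute)
    fc_conditions[[paste0("state", s)]] <- state_mats_adj[[s]]
  }

  ## stage 5: associations -------------------------------------------
  assoc <- associate(profiles, response, ofc, temporal = temporal,
                     fc_matrices = fc_conditions)
  warnings_log <- c(warnings_log, attr(assoc, "warnings"))

  res <- structure(list(
    config = config,
    cohort_ids = ids,
    response = response,
    static_fc = static_raw,
    static_adjusted = adj$adjusted,
    group_fc = adj$group_mean,
    overall_fc = ofc,
    static_variance = static_var,
    lambda_by_subject = lambda_by_subject,
    windows = windows,
    states = decomp,
    temporal = temporal,
    state_variance = state_var,
    profiles = profiles,
    associations = assoc,
    warnings = warnings_log,
    elapsed_s = as.numeric(Sys.time() - t0, units = "secs")),
    class = "dfc_study")
  res
}

#' @export
print.dfc_study <- function(x, ...) {
  cat("Dynamic-connectivity brain-state analysis\n")
  cat("  subjects: ", length(x$cohort_ids), ", windows/subject: ",
      length(x$windows[[1L]]$matrices), ", states: k = ", x$states$k,
      "\n", sep = "")
  occ <- colMeans(do.call(rbind, lapply(x$temporal, `[[`, "fraction_time")))
  cat("  mean occupancy: ",
      paste(sprintf("%s %.1f%%", names(occ), 100 * occ), collapse = ", "),
      "\n", sep = "")
  cat("  mean edge variance: static ", format(x$static_variance$mean_variance,
                                              digits = 3), ", ",
      paste(sprintf("%s %s", names(x$state_variance),
                    format(x$state_variance, digits = 3)), collapse = ", "),
      "\n", sep = "")
  sig <- x$associations[x$associations$p_fdr < 0.05, , drop = FALSE]
  cat("  associations with response (p_fdr < 0.05): ", nrow(sig), "\n",
      sep = "")
  invisible(x)
}

#' @export
summary.dfc_study <- function(object, ...) {
  x <- object
  occ <- do.call(rbind, lapply(x$temporal, `[[`, "fraction_time"))
  dw <- do.call(rbind, lapply(x$temporal, `[[`, "mean_dwell_min"))
  tr <- vapply(x$temporal, `[[`, 0L, "n_transitions")
  glob <- x$associations[is.na(x$associations$node) &
                           x$associations$metric %in%
                           c("global_efficiency", "assortativity"), ,
                         drop = FALSE]
  out <- list(
    n_subjects = length(x$cohort_ids),
    k = x$states$k,
    silhouette_by_k = x$states$silhouette_by_k,
    bic_by_k = x$states$bic_by_k,
    occupancy_mean = colMeans(occ),
    occupancy_sd = apply(occ, 2L, stats::sd),
    dwell_mean_min = colMeans(dw, na.rm = TRUE),
    transitions_mean = mean(tr),
    transitions_sd = stats::sd(tr),
    static_mean_variance = x$static_variance$mean_variance,
    state_mean_variance = x$state_variance,
    global_associations = glob,
    warnings = x$warnings)
  class(out) <- "summary.dfc_study"
  out
}

#' @export
print.summary.dfc_study <- function(x, ...) {
  cat("Brain-state decomposition of ", x$n_subjects, " subjects: k = ",
      x$k, "\n", sep = "")
  cat("  silhouette by k:",
      paste(sprintf("%s:%.3f", names(x$silhouette_by_k), x$silhouette_by_k),
            collapse = "  "), "\n")
  for (s in seq_along(x$occupancy_mean)) {
    cat(sprintf("  state %d: occupancy %.2f +/- %.2f %%, mean dwell %.2f min\n",
                s, 100 * x$occupancy_mean[s], 100 * x$occupancy_sd[s],
                x$dwell_mean_min[s]))
  }
  cat(sprintf("  transitions: %.2f +/- %.2f\n", x$transitions_mean,
              x$transitions_sd))
  cat(sprintf("  mean edge variance: static %.4f; %s\n",
              x$static_mean_variance,
              paste(sprintf("%s %.4f", names(x$state_mean_variance),
                            x$state_mean_variance), collapse = ", ")))
  cat("  global metric associations with response:\n")
  g <- x$global_associations
  for (i in seq_len(nrow(g))) {
    cat(sprintf("    %-18s %-7s r = %+.3f [%+.3f, %+.3f], p = %.4f (n = %d)\n",
                g$metric[i], g$state[i], g$r_partial[i], g$ci_low[i],
                g$ci_high[i], g$p_value[i], g$n_used[i]))
  }
  if (length(x$warnings)) {
    cat("  notes:\n")
    for (wmsg in x$warnings) cat("    - ", wmsg, "\n", sep = "")
  }
  invisible(x)
}

#' Scatter plot of the headline association
#'
#' Assortativity AUC against DBS response, one panel per condition
#' (static and each state), mirroring the study's headline scatter.
#'
#' @param x A \code{dfc_study}.
#' @param metric Metric AUC to plot (default \code{"assortativity"}).
#' @param ... Passed to \code{plot}.
#' @return \code{x}, invisibly.
#' @export
plot.dfc_study <- function(x, metric = "assortativity", ...) {
  conds <- names(x$profiles)
  op <- graphics::par(mfrow = c(1, length(conds)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (cond in conds) {
    prof <- x$profiles[[cond]]
    v <- vapply(prof, function(p) p$auc[[metric]], 0)
    resp <- x$response[names(v)]
    ok <- is.finite(v)
    graphics::plot(v[ok], resp[ok], xlab = paste(metric, "AUC"),
                   ylab = "UPDRS-III improvement [%]", main = cond,
                   pch = 19, ...)
    if (sum(ok) > 2) graphics::abline(stats::lm(resp[ok] ~ v[ok]), lty = 2)
  }
  invisible(x)
}

#' Save every artifact of a fitted study to an output tree
#'
#' Writes the on-disk layout consumed by the stage-wise command line:
#' static matrices and overall-FC table, per-subject windowed matrices
#' (long CSV) and selected penalties, state labels, centroids, median
#' matrices and temporal statistics, graph AUC tables, the association
#' results, and a JSON run manifest with the config echo, seed, package
#' version, per-file MD5 hashes and accumulated warnings.
#'
#' @param study A \code{dfc_study}.
#' @param dir Output directory.
#' @return \code{dir}, invisibly.
#' @export
save_study <- function(study, dir) {
  stopifnot(inherits(study, "dfc_study"))
  for (d in file.path(dir, c("static", "dynamic", "states", "graph",
                             "associate"))) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }
  ids <- study$cohort_ids
  for (id in ids) {
    write_matrix(study$static_adjusted[[id]],
                 file.path(dir, "static", paste0(id, "_fc.tsv")))
  }
  write_matrix(study$group_fc, file.path(dir, "static", "group_fc.tsv"))
  utils::write.csv(data.frame(subject_id = ids,
                              overall_fc = study$overall_fc[ids],
                              response = study$response[ids]),
                   file.path(dir, "static", "overall_fc.csv"),
                   row.names = FALSE, quote = FALSE)
  write_matrix(study$static_variance$variance_matrix,
               file.path(dir, "static", "edge_variance.tsv"))
  ## dynamic stage
  utils::write.csv(data.frame(subject_id = ids,
                              lambda = study$lambda_by_subject[ids]),
                   file.path(dir, "dynamic", "lambda.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(taper = study$windows[[1L]]$taper),
                   file.path(dir, "dynamic", "taper.csv"),
                   row.names = FALSE, quote = FALSE)
  for (id in ids) {
    write_windowed(study$windows[[id]],
                   file.path(dir, "dynamic", paste0(id, "_windows.csv")))
  }
  ## states stage
  lab_rows <- do.call(rbind, lapply(ids, function(id) {
    data.frame(subject_id = id,
               window = seq_along(study$states$labels[[id]]),
               state = study$states$labels[[id]], stringsAsFactors = FALSE)
  }))
  utils::write.csv(lab_rows, file.path(dir, "states", "labels.csv"),
                   row.names = FALSE, quote = FALSE)
  for (s in seq_len(study$states$k)) {
    write_matrix(study$states$centroid_matrices[[s]],
                 file.path(dir, "states", sprintf("centroid_state%d.tsv", s)))
    for (id in ids) {
      m <- study$states$state_matrices[[id]][[s]]
      if (!is.null(m)) {
        write_matrix(m, file.path(dir, "states",
                                  sprintf("%s_state%d_median.tsv", id, s)))
      }
    }
  }
  sel <- data.frame(k = as.integer(names(study$states$silhouette_by_k)),
                    silhouette = study$states$silhouette_by_k,
                    bic = study$states$bic_by_k)
  utils::write.csv(sel, file.path(dir, "states", "selection.csv"),
                   row.names = FALSE, quote = FALSE)
  tmp <- do.call(rbind, lapply(ids, function(id) {
    t <- study$temporal[[id]]
    data.frame(subject_id = id, state = seq_along(t$fraction_time),
               fraction_time = t$fraction_time,
               mean_dwell_min = t$mean_dwell_min,
               n_transitions = t$n_transitions, stringsAsFactors = FALSE)
  }))
  utils::write.csv(tmp, file.path(dir, "states", "temporal.csv"),
                   row.names = FALSE, quote = FALSE)
  ## graph stage: long AUC table
  utils::write.csv(auc_table(study$profiles),
                   file.path(dir, "graph", "auc.csv"),
                   row.names = FALSE, quote = FALSE)
  ## associations + headline scatter data
  utils::write.csv(study$associations,
                   file.path(dir, "associate", "associations.csv"),
                   row.names = FALSE, quote = FALSE)
  sc <- do.call(rbind, lapply(names(study$profiles), function(cond) {
    v <- vapply(study$profiles[[cond]], function(p) p$auc[["assortativity"]], 0)
    data.frame(subject_id = names(v), condition = cond,
               assortativity_auc = v,
               response = study$response[names(v)],
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(sc, file.path(dir, "associate", "scatter_assortativity.csv"),
                   row.names = FALSE, quote = FALSE)
  write_manifest(study, dir)
  invisible(dir)
}

#' Long-format AUC table of a profile set
#' @param profiles Nested list condition -> subject -> graph_profile.
#' @return Data.frame: subject, condition, metric, node, auc.
#' @export
auc_table <- function(profiles) {
  do.call(rbind, lapply(names(profiles), function(cond) {
    do.call(rbind, lapply(names(profiles[[cond]]), function(id) {
      auc <- profiles[[cond]][[id]]$auc
      do.call(rbind, lapply(names(auc), function(m) {
        v <- auc[[m]]
        data.frame(subject_id = id, condition = cond, metric = m,
                   node = if (is.null(names(v))) NA_character_ else names(v),
                   auc = as.numeric(v), stringsAsFactors = FALSE)
      }))
    }))
  }))
}

#' Write a windowed series as one long-format CSV
#' @param wfc A \code{windowed_fc}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_windowed <- function(wfc, path) {
  labs <- colnames(wfc$matrices[[1L]])
  pr <- which(upper.tri(wfc$matrices[[1L]]), arr.ind = TRUE)
  rows <- do.call(rbind, lapply(seq_along(wfc$matrices), function(i) {
    data.frame(window = i, start = wfc$window_starts[i],
               region_i = labs[pr[, 1L]], region_j = labs[pr[, 2L]],
               value = wfc$matrices[[i]][upper.tri(wfc$matrices[[i]])],
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a windowed series written by \code{\link{write_windowed}}
#' @param path CSV path.
#' @return A \code{windowed_fc} (taper/lambda not restored).
#' @export
read_windowed <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  labs <- unique(c(df$region_i, df$region_j))
  nw <- max(df$window)
  mats <- lapply(seq_len(nw), function(i) {
    sub <- df[df$window == i, ]
    m <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
    m[cbind(match(sub$region_i, labs), match(sub$region_j, labs))] <- sub$value
    m + t(m)
  })
  starts <- vapply(seq_len(nw), function(i) df$start[df$window == i][1L], 0)
  structure(list(matrices = mats, window_starts = starts,
                 lambda_used = NA_real_, taper = NULL),
            class = "windowed_fc")
}

write_manifest <- function(study, dir, error = NULL) {
  files <- list.files(dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(dir, "manifest.json"))
  hashes <- tools::md5sum(files)
  names(hashes) <- sub(paste0("^", gsub("([.\\\\+*?^$(){}|\\[\\]])",
                                        "\\\\\\1", dir), "/?"), "",
                       names(hashes))
  manifest <- list(
    package_version = as.character(utils::packageVersion("dynstates")),
    seed = study$config$rng_seed,
    config = unclass(study$config),
    files = as.list(hashes),
    warnings = as.list(study$warnings),
    error = error,
    elapsed_s = study$elapsed_s)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}

#' Run the full pipeline from a cohort directory or simulation
#'
#' Reads (or simulates) a cohort, fits \code{\link{dfc_study}} and, when
#' \code{output_dir} is set in the config, saves the complete output
#' tree with a run manifest. A manifest is written even when a stage
#' fails, recording the failing stage.
#'
#' @param config A \code{\link{run_config}}.
#' @param cohort_dir Directory with \code{phenotypes.csv} and per-subject
#'   TSVs; ignored when \code{simulate} is \code{TRUE}.
#' @param simulate Simulate a cohort instead of reading one.
#' @param n_subjects Cohort size when simulating.
#' @return The fitted \code{dfc_study}.
#' @export
run_pipeline <- function(config = run_config(), cohort_dir = NULL,
                         simulate = FALSE, n_subjects = 12L) {
  ch <- if (simulate) {
    generate_cohort(n_subjects = n_subjects, tr_seconds = config$tr_seconds,
                    ar_coef = config$ar_coef,
                    thresholds = threshold_grid(config),
                    seed = stage_seed(config$rng_seed, "simulate"))
  } else {
    if (is.null(cohort_dir)) stop("either cohort_dir or simulate must be given")
    read_cohort(cohort_dir, config$tr_seconds)
  }
  study <- tryCatch(dfc_study(ch, config), error = function(e) e)
  if (inherits(study, "error")) {
    if (!is.null(config$output_dir)) {
      dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
      fake <- list(config = config, warnings = character(), elapsed_s = NA)
      write_manifest(fake, config$output_dir,
                     error = conditionMessage(study))
    }
    stop("pipeline failed: ", conditionMessage(study))
  }
  if (!is.null(config$output_dir)) save_study(study, config$output_dir)
  study
}
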