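#' Percent improvement from DBS
#'
#' Response to stimulation at follow-up, quantified as the percentage
#' improvement of the UPDRS-III motor score between the
#' medication-ON/stimulation-OFF and medication-ON/stimulation-ON
#' assessments: \code{100 * (onoff - onon) / onoff}.
#'
#' @param onoff UPDRS-III ON-OFF score (> 0).
#' @param onon UPDRS-III ON-ON score (>= 0).
#' @return Percent improvement (vectorised).
#' @export
dbs_response <- function(onoff, onon) {
  if (any(onoff <= 0)) stop("ON-OFF score must be positive")
  if (any(onon < 0)) stop("ON-ON score must be non-negative")
  100 * (onoff - onon) / onoff
}

#' Pearson partial correlation with covariate control
#'
#' x and y are each residualised (with intercept) against the covariate
#' columns Z; the product-moment correlation of the residuals is
#' returned with a t-based p-value on n - 2 - ncol(Z) degrees of freedom
#' and a Fisher-z 95% confidence interval using variance
#' 1 / (n - 3 - ncol(Z)).
#'
#' @param x,y Numeric vectors.
#' @param z Covariate matrix/data.frame (may be \code{NULL} or have zero
#'   columns, giving the plain correlation).
#' @param conf_level Confidence level for the interval.
#' @return List with \code{r}, \code{p}, \code{ci} (length 2), \code{df},
#'   \code{n}.
#' @export
partial_correlation <- function(x, y, z = NULL, conf_level = 0.95) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y differ in length")
  nz <- if (is.null(z)) 0L else ncol(as.matrix(z))
  if (n <= nz + 2L) stop("insufficient observations for ", nz, " covariates")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y")
  }
  if (nz > 0L) {
    Z <- cbind(1, as.matrix(z))
    q <- qr(Z)
    if (q$rank < ncol(Z)) stop("rank-deficient covariate design")
    x <- x - Z %*% qr.coef(q, x)
    y <- y - Z %*% qr.coef(q, y)
  }
  r <- as.numeric(stats::cor(x, y))
  df <- n - 2L - nz
  tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df)
  se <- 1 / sqrt(n - 3L - nz)
  zcrit <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- tanh(atanh(min(max(r, -1 + 1e-15), 1 - 1e-15)) + c(-1, 1) * zcrit * se)
  list(r = r, p = p, ci = ci, df = df, n = n)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; input order is restored and adjusted values
#' are capped at 1 and never below the raw values.
#'
#' @param p Vector of p-values in (0, 1].
#' @return Adjusted p-values in the input order.
#' @export
fdr_bh <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

.assoc_row <- function(metric, state, node, pc) {
  data.frame(metric = metric, state = state, node = node,
             r_partial = pc$r, ci_low = pc$ci[1L], ci_high = pc$ci[2L],
             p_value = pc$p, p_fdr = NA_real_, n_used = pc$n,
             stringsAsFactors = FALSE)
}

#' Covariate-controlled associations between network measures and response
#'
#' For every target quantity the Pearson partial correlation with the
#' clinical response is computed: graph-metric AUCs and FC edges control
#' for the subject's overall functional connectivity (guarding the
#' proportional-threshold and gross-connectivity confound); temporal
#' statistics use no additional covariate. FDR correction is applied
#' within each local-metric family (one family per metric per state,
#' across nodes) and within each FC-edge family (one per state, across
#' edges); global-metric and temporal tests are reported uncorrected
#' (\code{p_fdr} = \code{p_value}). Subjects missing a state are
#' excluded pairwise, with \code{n_used} recording the subjects that
#' entered each test.
#'
#' @param profiles Named list (condition -> named list subject ->
#'   \code{graph_profile}); conditions are e.g. \code{"static"},
#'   \code{"state1"}, \code{"state2"}. Subjects missing a condition are
#'   simply absent from its inner list.
#' @param response Named numeric vector of response percentages.
#' @param overall_fc_by_subject Named numeric vector of overall-FC
#'   scalars.
#' @param temporal Optional named list subject -> output of
#'   \code{\link{temporal_stats}}.
#' @param fc_matrices Optional named list (condition -> named list
#'   subject -> connectivity matrix) for edge-wise association.
#' @param min_n Minimum subjects required per test (default 8).
#' @return Data.frame of association results, one row per test, plus an
#'   attribute \code{warnings} listing skipped families.
#' @export
associate <- function(profiles, response, overall_fc_by_subject,
                      temporal = NULL, fc_matrices = NULL, min_n = 8L) {
  if (stats::sd(response) == 0) stop("response has zero variance")
  rows <- list()
  notes <- character()
  add <- function(df) rows[[length(rows) + 1L]] <<- df
  for (cond in names(profiles)) {
    prof <- profiles[[cond]]
    ids <- intersect(names(prof), names(response))
    if (length(ids) < min_n) {
      notes <- c(notes, paste0("condition '", cond, "' skipped: only ",
                               length(ids), " usable subjects"))
      next
    }
    resp <- response[ids]
    ofc <- overall_fc_by_subject[ids]
    glob_metrics <- intersect(c("global_efficiency", "assortativity"),
                              names(prof[[1L]]$auc))
    for (gm in glob_metrics) {
      v <- vapply(prof[ids], function(p) p$auc[[gm]], 0)
      ok <- is.finite(v)
      if (sum(ok) < min_n) {
        notes <- c(notes, paste0(gm, " (", cond, ") skipped: too few defined AUCs"))
        next
      }
      pc <- partial_correlation(v[ok], resp[ok], ofc[ok])
      d <- .assoc_row(gm, cond, NA_character_, pc)
      d$p_fdr <- d$p_value
      add(d)
    }
    for (lm in intersect(c("clustering", "betweenness"), names(prof[[1L]]$auc))) {
      aucs <- t(vapply(prof[ids], function(p) p$auc[[lm]],
                       numeric(length(prof[[1L]]$auc[[lm]]))))
      fam <- list()
      for (j in seq_len(ncol(aucs))) {
        v <- aucs[, j]
        ok <- is.finite(v)
        if (sum(ok) < min_n) next
        pc <- partial_correlation(v[ok], resp[ok], ofc[ok])
        fam[[length(fam) + 1L]] <- .assoc_row(lm, cond, colnames(aucs)[j], pc)
      }
      if (length(fam)) {
        fam <- do.call(rbind, fam)
        fam$p_fdr <- fdr_bh(fam$p_value)
        add(fam)
      }
    }
  }
  if (!is.null(fc_matrices)) {
    for (cond in names(fc_matrices)) {
      mats <- fc_matrices[[cond]]
      ids <- intersect(names(mats), names(response))
      if (length(ids) < min_n) {
        notes <- c(notes, paste0("FC edges (", cond, ") skipped: only ",
                                 length(ids), " usable subjects"))
        next
      }
      resp <- response[ids]
      ofc <- overall_fc_by_subject[ids]
      E <- t(vapply(mats[ids], upper_tri_vec,
                    numeric(length(upper_tri_vec(mats[[ids[1L]]])))))
      labs <- colnames(mats[[ids[1L]]])
      pr <- which(upper.tri(mats[[ids[1L]]]), arr.ind = TRUE)
      edge_names <- paste0(labs[pr[, 1L]], "-", labs[pr[, 2L]])
      fam <- list()
      for (j in seq_len(ncol(E))) {
        if (stats::sd(E[, j]) == 0) next
        pc <- partial_correlation(E[, j], resp, ofc)
        fam[[length(fam) + 1L]] <- .assoc_row("fc_edge", cond, edge_names[j], pc)
      }
      if (length(fam)) {
        fam <- do.call(rbind, fam)
        fam$p_fdr <- fdr_bh(fam$p_value)
        add(fam)
      }
    }
  }
  if (!is.null(temporal)) {
    ids <- intersect(names(temporal), names(response))
    if (length(ids) >= min_n) {
      resp <- response[ids]
      k <- length(temporal[[ids[1L]]]$fraction_time)
      for (s in seq_len(k)) {
        v <- vapply(temporal[ids], function(t) t$fraction_time[s], 0)
        if (stats::sd(v) > 0) {
          d <- .assoc_row("fraction_time", paste0("state", s), NA_character_,
                          partial_correlation(v, resp, NULL))
          d$p_fdr <- d$p_value
          add(d)
        }
        dw <- vapply(temporal[ids], function(t) t$mean_dwell_min[s], 0)
        ok <- is.finite(dw)
        if (sum(ok) >= min_n && stats::sd(dw[ok]) > 0) {
          d <- .assoc_row("mean_dwell", paste0("state", s), NA_character_,
                          partial_correlation(dw[ok], resp[ok], NULL))
          d$p_fdr <- d$p_value
          add(d)
        }
      }
      tr <- vapply(temporal[ids], function(t) as.numeric(t$n_transitions), 0)
      if (stats::sd(tr) > 0) {
        d <- .assoc_row("n_transitions", "all", NA_character_,
                        partial_correlation(tr, resp, NULL))
        d$p_fdr <- d$p_value
        add(d)
      }
    } else {
      notes <- c(notes, "temporal tests skipped: too few subjects")
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(metric = character(), state = character(), node = character(),
               r_partial = numeric(), ci_low = numeric(), ci_high = numeric(),
               p_value = numeric(), p_fdr = numeric(), n_used = integer(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "warnings") <- notes
  out
}
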