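#' Read a subject's region time-series matrix
#'
#' Reads a tab-separated text file holding one subject's region (ROI/IC)
#' time courses: one header row of region labels, then T numeric rows
#' (time points) by R columns (regions).
#'
#' @param path Path to a TSV file.
#' @param tr_seconds Repetition time in seconds (time between rows).
#' @param subject_id Subject identifier; defaults to the file name without
#'   extension.
#' @param network_labels Optional character vector of length R assigning each
#'   region to a functional network (e.g. \code{"DMN"}, \code{"SM"}).
#' @return A \code{subject_ts} object: list with \code{subject_id},
#'   \code{data} (T x R numeric matrix, column names = region labels),
#'   \code{tr_seconds}, \code{region_labels}, \code{network_labels}.
#' @export
read_timeseries <- function(path, tr_seconds, subject_id = NULL,
                            network_labels = NULL) {
  if (!file.exists(path)) stop("time-series file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 2L) stop("time-series file has no data rows: ", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  ncell <- lengths(body)
  if (any(ncell != length(header))) {
    bad <- which(ncell != length(header))[1L]
    stop("ragged time-series file: row ", bad + 1L, " has ", ncell[bad],
         " cells, header has ", length(header))
  }
  vals <- suppressWarnings(lapply(body, as.numeric))
  for (i in seq_along(vals)) {
    j <- which(is.na(vals[[i]]) & !(toupper(body[[i]]) %in% c("NA", "NAN")))
    if (length(j)) {
      stop("non-numeric cell in time-series file at row ", i + 1L,
           ", column ", j[1L], " (region '", header[j[1L]], "'): '",
           body[[i]][j[1L]], "'")
    }
  }
  mat <- do.call(rbind, vals)
  colnames(mat) <- header
  if (ncol(mat) < 2L) stop("time series needs at least 2 regions, got ", ncol(mat))
  if (anyNA(mat)) stop("missing values in time-series file: ", path)
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  subject_ts(mat, tr_seconds, subject_id = subject_id,
             network_labels = network_labels)
}

#' Construct a subject time-series object
#'
#' @param data T x R numeric matrix, time in rows, regions in columns.
#' @inheritParams read_timeseries
#' @return A \code{subject_ts} object.
#' @export
subject_ts <- function(data, tr_seconds, subject_id = "subj",
                       network_labels = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) < 2L || ncol(data) < 2L) {
    stop("time series must be at least 2 x 2 (got ", nrow(data), " x ",
         ncol(data), ")")
  }
  if (anyNA(data)) stop("time series contains missing values")
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0) {
    stop("tr_seconds must be a single positive number")
  }
  if (is.null(colnames(data))) {
    colnames(data) <- sprintf("R%02d", seq_len(ncol(data)))
  }
  if (!is.null(network_labels) && length(network_labels) != ncol(data)) {
    stop("network_labels must have one entry per region")
  }
  structure(
    list(subject_id = as.character(subject_id), data = data,
         tr_seconds = as.numeric(tr_seconds),
         region_labels = colnames(data),
         network_labels = network_labels),
    class = "subject_ts")
}

#' @export
print.subject_ts <- function(x, ...) {
  cat("Subject time series '", x$subject_id, "': ", nrow(x$data),
      " time points x ", ncol(x$data), " regions, TR = ", x$tr_seconds,
      " s\n", sep = "")
  invisible(x)
}

#' Write a subject time series to TSV
#'
#' @param ts A \code{subject_ts} object.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "subject_ts"))
  utils::write.table(format(ts$data, digits = 15, trim = TRUE,
                            scientific = FALSE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.pheno_required <- c("subject_id", "age_years", "gender", "updrs3_on_preop",
                     "mean_framewise_displacement", "updrs3_onoff",
                     "updrs3_onon")

#' Read the cohort phenotype table
#'
#' Comma-separated table with one row per subject. Required columns:
#' \code{subject_id}, \code{age_years}, \code{gender} (0/1),
#' \code{updrs3_on_preop}, \code{mean_framewise_displacement},
#' \code{updrs3_onoff}, \code{updrs3_onon}. Extra columns are carried
#' through untouched.
#'
#' @param path Path to a CSV file.
#' @return A data.frame, one row per subject.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_phenotypes(df)
}

#' Validate a phenotype data.frame
#'
#' @param df data.frame with the columns documented in
#'   \code{\link{read_phenotypes}}.
#' @return \code{df}, with \code{subject_id} coerced to character.
#' @export
validate_phenotypes <- function(df) {
  missing_cols <- setdiff(.pheno_required, names(df))
  if (length(missing_cols)) {
    stop("phenotype table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df$subject_id <- as.character(df$subject_id)
  dup <- df$subject_id[duplicated(df$subject_id)]
  if (length(dup)) {
    stop("duplicate subject_id in phenotype table: ",
         paste(unique(dup), collapse = ", "))
  }
  num_cols <- setdiff(.pheno_required, "subject_id")
  for (cc in num_cols) {
    if (!is.numeric(df[[cc]])) stop("phenotype column '", cc, "' is not numeric")
  }
  if (any(df$updrs3_onoff < 0) || any(df$updrs3_onon < 0)) {
    stop("UPDRS-III scores must be non-negative")
  }
  if (!all(df$gender %in% c(0, 1))) stop("gender must be coded 0/1")
  df
}

#' Write a phenotype table to CSV
#' @param df Phenotype data.frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_phenotypes <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a square labelled matrix to TSV
#'
#' Used for connectivity matrices (correlation scale) and binary
#' adjacency matrices. Region labels go in the header and first column,
#' so the file reads back with \code{\link{read_matrix}} to 1e-12.
#'
#' @param m Square symmetric numeric matrix.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_matrix <- function(m, path) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("matrix must be square")
  if (max(abs(m - t(m))) > 1e-10) {
    stop("matrix is asymmetric beyond 1e-10 (max |m - t(m)| = ",
         format(max(abs(m - t(m)))), ")")
  }
  if (is.null(colnames(m))) colnames(m) <- sprintf("R%02d", seq_len(ncol(m)))
  rownames(m) <- colnames(m)
  df <- data.frame(region = rownames(m),
                   format(m, digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square labelled matrix from TSV
#' @param path Path written by \code{\link{write_matrix}}.
#' @return Named square numeric matrix.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1L]]
  if (nrow(m) != ncol(m)) stop("matrix file is not square: ", path)
  m
}

#' Assemble a cohort from time-series objects and phenotypes
#'
#' Checks that every subject shares the region count, region order and TR
#' of the first subject, and that phenotype IDs match the time-series IDs
#' exactly.
#'
#' @param ts_list List of \code{subject_ts} objects.
#' @param phenotypes Phenotype data.frame (see \code{\link{read_phenotypes}}).
#' @return A \code{dfc_cohort} object: list with \code{ts} (named list),
#'   \code{phenotypes}, \code{tr_seconds}, \code{region_labels},
#'   \code{network_labels}.
#' @export
cohort <- function(ts_list, phenotypes) {
  stopifnot(length(ts_list) >= 1L)
  phenotypes <- validate_phenotypes(phenotypes)
  ref <- ts_list[[1L]]
  for (ts in ts_list) {
    stopifnot(inherits(ts, "subject_ts"))
    if (ncol(ts$data) != ncol(ref$data) ||
        !identical(ts$region_labels, ref$region_labels)) {
      stop("subject '", ts$subject_id,
           "' has a different region set/order than subject '",
           ref$subject_id, "'")
    }
    if (ts$tr_seconds != ref$tr_seconds) {
      stop("subject '", ts$subject_id, "' has TR ", ts$tr_seconds,
           " but cohort TR is ", ref$tr_seconds)
    }
  }
  ids <- vapply(ts_list, `[[`, "", "subject_id")
  if (anyDuplicated(ids)) stop("duplicate subject IDs in time-series list")
  names(ts_list) <- ids
  extra <- setdiff(ids, phenotypes$subject_id)
  orphan <- setdiff(phenotypes$subject_id, ids)
  if (length(extra) || length(orphan)) {
    stop("subject IDs do not match between time series and phenotypes.",
         if (length(extra)) paste0(" Missing phenotypes: ",
                                   paste(extra, collapse = ", "), "."),
         if (length(orphan)) paste0(" Phenotypes without time series: ",
                                    paste(orphan, collapse = ", "), "."))
  }
  phenotypes <- phenotypes[match(ids, phenotypes$subject_id), , drop = FALSE]
  rownames(phenotypes) <- NULL
  structure(list(ts = ts_list, phenotypes = phenotypes,
                 tr_seconds = ref$tr_seconds,
                 region_labels = ref$region_labels,
                 network_labels = ref$network_labels),
            class = "dfc_cohort")
}

#' @export
print.dfc_cohort <- function(x, ...) {
  cat("Cohort: ", length(x$ts), " subjects, ",
      length(x$region_labels), " regions, T = ",
      nrow(x$ts[[1L]]$data), ", TR = ", x$tr_seconds, " s\n", sep = "")
  invisible(x)
}

#' Read a cohort from a directory layout
#'
#' Expects \code{phenotypes.csv} plus one \code{<subject_id>.tsv} time-series
#' file per subject, as written by \code{\link{write_cohort}}.
#'
#' @param dir Cohort directory.
#' @param tr_seconds TR in seconds for all subjects.
#' @param network_labels Optional per-region network labels.
#' @return A \code{dfc_cohort}.
#' @export
read_cohort <- function(dir, tr_seconds, network_labels = NULL) {
  pheno_path <- file.path(dir, "phenotypes.csv")
  if (!file.exists(pheno_path)) {
    stop("phenotype file not found: ", pheno_path)
  }
  ph <- read_phenotypes(pheno_path)
  nl <- network_labels
  nl_path <- file.path(dir, "networks.tsv")
  if (is.null(nl) && file.exists(nl_path)) {
    nldf <- utils::read.delim(nl_path, stringsAsFactors = FALSE)
    nl <- nldf$network
  }
  ts_list <- lapply(ph$subject_id, function(id) {
    read_timeseries(file.path(dir, paste0(id, ".tsv")), tr_seconds,
                    subject_id = id, network_labels = nl)
  })
  cohort(ts_list, ph)
}

#' Write a cohort to a directory layout
#'
#' @param ch A \code{dfc_cohort}.
#' @param dir Output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(ch, dir) {
  stopifnot(inherits(ch, "dfc_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_phenotypes(ch$phenotypes, file.path(dir, "phenotypes.csv"))
  for (ts in ch$ts) write_timeseries(ts, file.path(dir, paste0(ts$subject_id, ".tsv")))
  if (!is.null(ch$network_labels)) {
    utils::write.table(data.frame(region = ch$region_labels,
                                  network = ch$network_labels),
                       file.path(dir, "networks.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Default run configuration
#'
#' All tunable parameters of the pipeline with their defaults: 22-TR
#' sliding window with a 3-TR Gaussian taper and 1-TR step, lambda grid for
#' the graphical lasso with 10 train/test repetitions, k-means over
#' k = 2..10 with 100 restarts, proportional thresholds 10..34% in 1%
#' steps, 100 rewired null graphs for small-worldness.
#'
#' @param ... Named overrides of any default field.
#' @return A \code{run_config} object (a list).
#' @export
run_config <- function(...) {
  cfg <- list(
    tr_seconds = 2.7,
    window_length_tr = 22L,
    taper_sigma_tr = 3,
    step_tr = 1L,
    lambda_grid = c(0.01, 0.03, 0.1, 0.3, 0.5),
    lambda_reps = 10L,
    k_min = 2L,
    k_max = 10L,
    kmeans_reps = 100L,
    threshold_min = 10,
    threshold_max = 34,
    threshold_step = 1,
    n_null_graphs = 100L,
    ar_coef = 0.3,
    rank_by_absolute = FALSE,
    edge_significance_mask = FALSE,
    rng_seed = 1L,
    output_dir = NULL
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  if (cfg$threshold_min <= 0 || cfg$threshold_max >= 100 ||
      cfg$threshold_max < cfg$threshold_min || cfg$threshold_step <= 0) {
    stop("threshold grid must be non-empty and inside (0, 100)")
  }
  if (cfg$window_length_tr < 2L) stop("window_length_tr must be >= 2")
  if (cfg$k_min < 2L || cfg$k_max < cfg$k_min) stop("invalid k range")
  class(cfg) <- "run_config"
  cfg
}

#' Threshold grid (percent) of a configuration
#' @param config A \code{run_config}.
#' @return Numeric vector of percentages.
#' @export
threshold_grid <- function(config) {
  seq(config$threshold_min, config$threshold_max, by = config$threshold_step)
}

#' Read a run configuration from a YAML or JSON file
#' @param path Path to a \code{.yaml}/\code{.yml} or \code{.json} file whose
#'   keys are \code{run_config} fields.
#' @return A \code{run_config}.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(run_config, vals)
}

#' Derive a reproducible child seed for a pipeline stage
#'
#' A single run seed is fanned out to per-stage seeds through a fixed hash
#' of the stage name, so changing one stage's draws cannot perturb another
#' stage.
#'
#' @param seed Integer run seed.
#' @param stage Stage name (character).
#' @return Integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 97)
  as.integer((as.numeric(seed) * 65539 + h) %% 2147483647)
}
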