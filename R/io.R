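## Wide-CSV cohort format: one row per sample, columns
## sample_id, group, run_index, t0001 ... tNNNN (zero-padded for lexical
## ordering; time-point indices are 1-based throughout).

t_col_names <- function(grid_length) {
  width <- max(4L, nchar(as.character(grid_length)))
  sprintf(paste0("t%0", width, "d"), seq_len(grid_length))
}

#' Write a cohort to wide CSV
#'
#' @param cohort a `cohort` object.
#' @param path output CSV path.
#' @param manifest_path optional path for a manifest CSV
#'   (`sample_id`, `group`, `run_index` only).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, manifest_path = NULL) {
  stopifnot(is_cohort(cohort))
  X <- cohort$X
  dt <- data.table::as.data.table(X)
  data.table::setnames(dt, t_col_names(ncol(X)))
  dt <- cbind(data.table::as.data.table(
    cohort$meta[, c("sample_id", "group", "run_index")]), dt)
  data.table::fwrite(dt, path)
  if (!is.null(manifest_path))
    data.table::fwrite(cohort$meta[, c("sample_id", "group", "run_index")],
                       manifest_path)
  invisible(path)
}

#' Read a cohort from wide CSV
#'
#' Validates the header (`sample_id`, `group`, `run_index`, then a complete
#' zero-padded `t...` sequence), group labels, uniqueness of sample ids and
#' numeric, finite, positive trace values; errors name the offending row or
#' column.
#'
#' @param path CSV path as written by [write_cohort()].
#' @return a `cohort` object (row order preserved; no generator ground
#'   truth).
#' @export
read_cohort <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  need <- c("sample_id", "group", "run_index")
  if (!identical(names(dt)[1:3], need))
    stop(sprintf("format error: first columns must be %s", paste(need, collapse = ", ")),
         call. = FALSE)
  tc <- names(dt)[-(1:3)]
  G <- length(tc)
  if (G < 2) stop("format error: no trace columns found", call. = FALSE)
  expect <- t_col_names(G)
  if (!identical(tc, expect)) {
    missing <- setdiff(expect, tc)
    extra <- setdiff(tc, expect)
    stop(sprintf("format error: trace columns do not form t0001..t%04d (missing: %s; unexpected: %s)",
                 G,
                 if (length(missing)) paste(utils::head(missing, 3), collapse = ", ") else "none",
                 if (length(extra)) paste(utils::head(extra, 3), collapse = ", ") else "none"),
         call. = FALSE)
  }
  for (cn in tc) {
    v <- dt[[cn]]
    if (!is.numeric(v))
      stop(sprintf("format error: non-numeric trace values in column %s", cn),
           call. = FALSE)
  }
  X <- as.matrix(dt[, tc, with = FALSE])
  bad <- which(!is.finite(X) | X <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("format error: non-finite or non-positive trace value at row %d, column %s",
                 bad[1, 1], tc[bad[1, 2]]), call. = FALSE)
  meta <- data.frame(sample_id = as.character(dt$sample_id),
                     group = as.character(dt$group),
                     run_index = dt$run_index, stringsAsFactors = FALSE)
  badg <- which(!meta$group %in% c("cancer", "control"))
  if (length(badg) > 0)
    stop(sprintf("format error: unknown group label '%s' at row %d",
                 meta$group[badg[1]], badg[1]), call. = FALSE)
  dup <- which(duplicated(meta$sample_id))
  if (length(dup) > 0)
    stop(sprintf("format error: duplicated sample_id '%s' at row %d",
                 meta$sample_id[dup[1]], dup[1]), call. = FALSE)
  new_cohort(X, meta)
}

#' Write a simulation configuration as a flat key-value text file
#'
#' Serializes a [sim_config()] to `key = value` lines with dotted namespaces
#' (tabular fields become indexed keys such as `shared_peaks.1.location`).
#'
#' @param config a `sim_config` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(config, path) {
  validate_sim_config(config)
  fl <- flatten_config(unclass(config))
  lines <- vapply(names(fl), function(k) {
    paste0(k, " = ", format(fl[[k]], digits = 17))
  }, character(1))
  writeLines(c("# gcvoc simulation configuration",
               paste0("# fingerprint = ", config_fingerprint(config)),
               lines), path)
  invisible(path)
}

#' Read a simulation configuration written by [write_sim_config()]
#'
#' @param path input path.
#' @return a `sim_config` object.
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, `[`, character(1), 2)
  get1 <- function(key, mode = "numeric") {
    v <- vals[keys == key]
    if (length(v) != 1) stop(sprintf("config file missing key '%s'", key), call. = FALSE)
    if (mode == "numeric") as.numeric(v) else v
  }
  get_table <- function(prefix, cols) {
    pat <- paste0("^", prefix, "\\.(\\d+)\\..*$")
    hits <- grep(pat, keys, value = TRUE)
    rows <- unique(as.integer(sub(pat, "\\1", hits, perl = TRUE)))
    if (length(rows) == 0)
      return(stats::setNames(as.data.frame(matrix(numeric(0), 0, length(cols))), cols))
    rows <- sort(rows)
    out <- lapply(cols, function(cn) {
      vapply(rows, function(i) get1(paste(prefix, i, cn, sep = ".")), numeric(1))
    })
    stats::setNames(as.data.frame(out), cols)
  }
  sim_config(
    n_cancer = get1("n_cancer"), n_control = get1("n_control"),
    grid_length = get1("grid_length"),
    sampling_interval = get1("sampling_interval"),
    shared_peaks = get_table("shared_peaks",
                             c("location", "width_sd", "amplitude_mean", "amplitude_cv")),
    marker_peak = list(
      location = get1("marker_peak.location"),
      width_sd = get1("marker_peak.width_sd"),
      amplitude_mean = get1("marker_peak.amplitude_mean"),
      amplitude_cv = get1("marker_peak.amplitude_cv"),
      prevalence_cancer = get1("marker_peak.prevalence_cancer"),
      prevalence_control = get1("marker_peak.prevalence_control")),
    secondary_effects = get_table("secondary_effects",
                                  c("location", "amplitude_shift")),
    rt_jitter_frac = get1("rt_jitter_frac"),
    baseline = list(start_level = get1("baseline.start_level"),
                    drift_sd = get1("baseline.drift_sd"),
                    slope_sd = get1("baseline.slope_sd")),
    noise_sd = get1("noise_sd"),
    ethanol_rt_mean = get1("ethanol_rt_mean"),
    ethanol_rt_sd = get1("ethanol_rt_sd"),
    sensitivity_mean = get1("sensitivity_mean"),
    sensitivity_sd = get1("sensitivity_sd"),
    seed = get1("seed")
  )
}
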