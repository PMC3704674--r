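#' Run configuration for the analysis pipeline
#'
#' Bundles paths, stage parameters and the seed for [run_pipeline()]. Stage
#' parameters default to the module defaults; the simulation model is a
#' [sim_config()] whose seed is tied to `seed`.
#'
#' @param out_dir output directory for stage artifacts (created if absent).
#' @param seed integer seed for all randomness.
#' @param cohort_path optional wide-CSV cohort to analyse; when `NULL`,
#'   stages read the cohort previously written by the `simulate` stage into
#'   `out_dir`.
#' @param sim a [sim_config()] for the `simulate` stage.
#' @param max_features,tolerance_floor,entry_threshold method-1 selection
#'   parameters.
#' @param protocol method-1 LOO protocol.
#' @param priors method-1 priors (`"equal"` or `"proportional"`).
#' @param max_factors method-2 sweep depth.
#' @param n_reps replicates for the `replicate` stage.
#' @param marker_window peak-detection window for the `preprocess` stage.
#' @param verbose emit progress messages to stderr.
#' @return an object of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, cohort_path = NULL,
                       sim = sim_config(seed = seed),
                       max_features = 9L, tolerance_floor = 0.001,
                       entry_threshold = 3.84,
                       protocol = "fixed_features", priors = "equal",
                       max_factors = 10L, n_reps = 20L,
                       marker_window = c(3100, 3300), verbose = TRUE) {
  if (!priors %in% c("equal", "proportional"))
    stop("priors must be 'equal' or 'proportional'", call. = FALSE)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 cohort_path = cohort_path, sim = sim,
                 max_features = max_features,
                 tolerance_floor = tolerance_floor,
                 entry_threshold = entry_threshold,
                 protocol = protocol, priors = priors,
                 max_factors = max_factors, n_reps = n_reps,
                 marker_window = marker_window, verbose = verbose),
            class = "run_config")
}

pipeline_log <- function(config, fmt, ...) {
  if (isTRUE(config$verbose)) message(sprintf(paste0("[gcvoc] ", fmt), ...))
}

pipeline_cohort <- function(config) {
  path <- config$cohort_path %||% file.path(config$out_dir, "cohort.csv")
  if (!file.exists(path))
    stop(sprintf("cohort file not found: %s (run the 'simulate' stage or set cohort_path)",
                 path), call. = FALSE)
  read_cohort(path)
}

prior_vector <- function(config, cohort) {
  if (config$priors == "equal") return(c(0.5, 0.5))
  tb <- table(cohort_labels(cohort))
  as.vector(tb / sum(tb))
}

write_run_summary <- function(config, command, artifacts, extra = list()) {
  summary <- c(list(command = command,
                    seed = config$seed,
                    config_fingerprint = config_fingerprint(config$sim),
                    artifacts = artifacts), extra)
  path <- file.path(config$out_dir, paste0(command, "_run.json"))
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

#' Run one stage of the chromatogram classification pipeline
#'
#' Ties the modules into the study's two end-to-end analyses. Stages:
#' \describe{
#'   \item{simulate}{generate a synthetic cohort; write wide CSV, manifest and
#'     the flat config file.}
#'   \item{preprocess}{group-average standardized chromatograms, per-sample
#'     marker-window peak calls, retention-time stability of the detected
#'     marker apexes.}
#'   \item{method1}{stepwise-LDA selection, fit and LOO-CV; model JSON and a
#'     confusion-table CSV (original and cross-validated blocks).}
#'   \item{method2}{PLS-DA factor sweep with LOO; sweep CSV and model JSON.}
#'   \item{evaluate}{method1 + method2 on the same cohort.}
#'   \item{replicate}{multi-seed replicate study; metrics CSV and summary
#'     JSON.}
#' }
#' Every stage embeds the configuration fingerprint and seed in a
#' `<stage>_run.json` summary so a run is reconstructable from its artifacts.
#'
#' @param config a [run_config()].
#' @param command one of `simulate`, `preprocess`, `method1`, `method2`,
#'   `evaluate`, `replicate`.
#' @return invisibly, a named list of artifact paths written.
#' @export
run_pipeline <- function(config, command) {
  stopifnot(inherits(config, "run_config"))
  valid <- c("simulate", "preprocess", "method1", "method2", "evaluate",
             "replicate")
  if (length(command) != 1L || !command %in% valid)
    stop(sprintf("usage: unknown command '%s' (expected one of %s)",
                 paste(command, collapse = ","), paste(valid, collapse = ", ")),
         call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  artifacts <- list()

  if (command == "simulate") {
    coh <- simulate_cohort(config$sim)
    artifacts$cohort <- out("cohort.csv")
    artifacts$manifest <- out("manifest.csv")
    artifacts$config <- out("sim_config.txt")
    write_cohort(coh, artifacts$cohort, artifacts$manifest)
    write_sim_config(config$sim, artifacts$config)
    pipeline_log(config, "simulated %d chromatograms (seed %d) -> %s",
                 nrow(coh$X), config$sim$seed, artifacts$cohort)
  } else if (command == "preprocess") {
    coh <- pipeline_cohort(config)
    gm <- data.frame(t = seq_len(ncol(coh$X)),
                     cancer_mean = group_mean_profile(coh, "cancer"),
                     control_mean = group_mean_profile(coh, "control"))
    artifacts$group_means <- out("group_means.csv")
    data.table::fwrite(gm, artifacts$group_means)
    pc <- peak_calls(coh, window = config$marker_window)
    artifacts$peak_calls <- out("peak_calls.csv")
    data.table::fwrite(pc, artifacts$peak_calls)
    meas <- pc[pc$measurable & !is.na(pc$location), ]
    if (nrow(meas) > 1) {
      stab <- assess_rt_stability(list(marker = meas$location))
      artifacts$rt_stability <- out("rt_stability.csv")
      data.table::fwrite(stab, artifacts$rt_stability)
    }
    pipeline_log(config, "peak calls: %d/%d cancer and %d/%d control measurable in [%d, %d]",
                 sum(pc$measurable[pc$group == "cancer"]),
                 sum(pc$group == "cancer"),
                 sum(pc$measurable[pc$group == "control"]),
                 sum(pc$group == "control"),
                 config$marker_window[1], config$marker_window[2])
  } else if (command == "method1") {
    coh <- pipeline_cohort(config)
    cv <- lda_loocv(coh, protocol = config$protocol,
                    max_features = config$max_features,
                    tolerance_floor = config$tolerance_floor,
                    entry_threshold = config$entry_threshold,
                    priors = prior_vector(config, coh))
    Z <- cohort_matrix(coh, standardize = TRUE)
    fit <- fisher_fit(Z[, cv$features$indices, drop = FALSE],
                      cohort_labels(coh),
                      priors = prior_vector(config, coh),
                      feature_indices = cv$features$indices)
    artifacts$model <- out("method1_model.json")
    jsonlite::write_json(list(feature_indices = fit$feature_indices,
                              coefficients = fit$coefficients,
                              threshold = fit$threshold,
                              priors = fit$priors,
                              wilks_lambda = cv$features$wilks,
                              seed = config$seed,
                              config_fingerprint = config_fingerprint(config$sim)),
                         artifacts$model, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    artifacts$table <- out("method1_confusion.csv")
    tab <- rbind(cbind(block = "original", as.data.frame(cv$within_confusion)),
                 cbind(block = "cross_validation_loo", as.data.frame(cv$confusion)))
    data.table::fwrite(tab, artifacts$table)
    pipeline_log(config, "method1: %d features, LOO sensitivity %.1f%%, specificity %.1f%%",
                 length(fit$feature_indices), cv$confusion$sensitivity,
                 cv$confusion$specificity)
  } else if (command == "method2") {
    coh <- pipeline_cohort(config)
    sw <- plsda_loocv_sweep(coh, max_factors = config$max_factors)
    artifacts$sweep <- out("method2_sweep.csv")
    data.table::fwrite(as.data.frame(sw), artifacts$sweep)
    fit <- plsda_fit(coh, n_factors = config$max_factors)
    artifacts$model <- out("method2_model.json")
    jsonlite::write_json(list(n_factors = fit$n_factors,
                              y_loadings = fit$y_loadings,
                              y_mean = fit$y_mean,
                              decision_threshold = fit$decision_threshold,
                              coefficients = fit$coefficients,
                              x_mean = fit$x_mean,
                              seed = config$seed,
                              config_fingerprint = config_fingerprint(config$sim)),
                         artifacts$model, auto_unbox = TRUE, digits = NA)
    pipeline_log(config, "method2: sweep of %d factors written", config$max_factors)
  } else if (command == "evaluate") {
    artifacts <- c(run_pipeline(config, "method1"),
                   run_pipeline(config, "method2"))
  } else if (command == "replicate") {
    rs <- replicate_study(config$sim, n_reps = config$n_reps,
                          protocol = config$protocol,
                          max_features = config$max_features,
                          max_factors = config$max_factors)
    artifacts$metrics <- out("replicate_metrics.csv")
    data.table::fwrite(rs$metrics, artifacts$metrics)
    artifacts$summary <- out("replicate_summary.json")
    jsonlite::write_json(list(summary = rs$summary, seeds = rs$seeds,
                              methods = rs$methods, protocol = rs$protocol,
                              config_fingerprint = rs$fingerprint),
                         artifacts$summary, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    pipeline_log(config, "replicate study over %d seeds written", length(rs$seeds))
  }

  artifacts$run_summary <- write_run_summary(config, command, artifacts)
  invisible(artifacts)
}
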