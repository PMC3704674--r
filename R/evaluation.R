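#' Two-group confusion matrix with sensitivity and specificity
#'
#' Tabulates predictions against true labels with cancer as the positive
#' class. Percentages are carried at full precision and printed to one decimal
#' place.
#'
#' @param labels true group labels (must contain both classes).
#' @param predictions predicted labels, same length.
#' @return an object of class `confusion_matrix`: counts `tp`, `fn`, `fp`,
#'   `tn`, and derived `sensitivity` / `specificity` percentages.
#' @examples
#' cm <- confusion(rep(c("cancer", "control"), c(24, 74)),
#'                 rep(c("cancer", "control", "cancer", "control"),
#'                     c(23, 1, 5, 69)))
#' cm$sensitivity  # 95.833...
#' @export
confusion <- function(labels, predictions) {
  if (length(labels) != length(predictions))
    stop("labels and predictions must have equal length", call. = FALSE)
  labels <- as.character(labels); predictions <- as.character(predictions)
  if (!all(c("cancer", "control") %in% labels))
    stop("labels must contain both classes", call. = FALSE)
  tp <- sum(labels == "cancer" & predictions == "cancer")
  fn <- sum(labels == "cancer" & predictions != "cancer")
  fp <- sum(labels == "control" & predictions == "cancer")
  tn <- sum(labels == "control" & predictions != "cancer")
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn,
                 n_cancer = tp + fn, n_control = fp + tn,
                 sensitivity = 100 * tp / (tp + fn),
                 specificity = 100 * tn / (fp + tn),
                 accuracy = 100 * (tp + tn) / length(labels)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  pct <- function(p) formatC(p, format = "f", digits = 1)
  cat("                 Predicted cancer  Predicted control  Total\n")
  cat(sprintf("  Cancer         %8d (%s%%)   %8d (%s%%)  %5d\n",
              x$tp, pct(100 * x$tp / x$n_cancer),
              x$fn, pct(100 * x$fn / x$n_cancer), x$n_cancer))
  cat(sprintf("  Control        %8d (%s%%)   %8d (%s%%)  %5d\n",
              x$fp, pct(100 * x$fp / x$n_control),
              x$tn, pct(100 * x$tn / x$n_control), x$n_control))
  cat(sprintf("  Sensitivity %s%%   Specificity %s%%\n",
              pct(x$sensitivity), pct(x$specificity)))
  invisible(x)
}

#' @export
as.data.frame.confusion_matrix <- function(x, ...) {
  data.frame(group = c("cancer", "control"),
             predicted_cancer = c(x$tp, x$fp),
             predicted_control = c(x$fn, x$tn),
             pct_correct = c(x$sensitivity, x$specificity))
}

## Shared single-seed end-to-end run used by the replicate harness.
run_methods_once <- function(config, seed, methods, protocol, max_features,
                             max_factors, prescreen) {
  cfg <- config
  cfg$seed <- as.integer(seed)
  coh <- simulate_cohort(cfg)
  rows <- list()
  if ("method1" %in% methods) {
    cv <- lda_loocv(coh, protocol = protocol, max_features = max_features,
                    prescreen = prescreen)
    rows[[length(rows) + 1L]] <- data.frame(
      seed = seed, method = "method1", n_factors = NA_integer_,
      loo_sensitivity = cv$confusion$sensitivity,
      loo_specificity = cv$confusion$specificity,
      loo_accuracy = cv$confusion$accuracy,
      within_sensitivity = cv$within_confusion$sensitivity,
      within_specificity = cv$within_confusion$specificity)
  }
  if ("method2" %in% methods) {
    sw <- plsda_loocv_sweep(coh, max_factors = max_factors)
    n <- nrow(coh$X)
    gs <- attr(sw, "group_sizes")
    rows[[length(rows) + 1L]] <- data.frame(
      seed = seed, method = "method2", n_factors = sw$n_factors,
      loo_sensitivity = sw$loo_cancer_pct,
      loo_specificity = sw$loo_control_pct,
      loo_accuracy = 100 * (sw$loo_cancer + sw$loo_control) / n,
      within_sensitivity = sw$within_cancer_pct,
      within_specificity = sw$within_control_pct)
  }
  do.call(rbind, rows)
}

#' Replicate simulation study of both classification pipelines
#'
#' Runs the full pipeline (simulate, standardize, select/fit, leave-one-out
#' cross-validate) once per seed for the requested methods and collects the
#' per-seed metrics, supporting the triangulation of the two independent
#' statistical approaches. Deterministic given `(config, seed_list)`.
#'
#' For method 2 the summary reports each seed at its best factor count among
#' `factor_band` (ties to the fewer factors), chosen by LOO specificity; the
#' per-factor rows are all retained in `metrics`.
#'
#' @param config a [sim_config()]; its `seed` field is overridden per
#'   replicate.
#' @param methods subset of `c("method1", "method2")`.
#' @param n_reps number of replicates (>= 1); used when `seed_list` is `NULL`.
#' @param seed_list explicit integer seeds, one per replicate.
#' @param protocol LOO protocol for method 1, see [lda_loocv()].
#' @param max_features,prescreen method-1 selection parameters.
#' @param max_factors method-2 sweep depth.
#' @param factor_band factor counts among which method 2's operating point is
#'   chosen for the summary (default 8-10).
#' @return an object of class `replicate_summary`: `metrics` (one row per
#'   seed, method and factor count), `summary` (median/min/max sensitivity and
#'   specificity per method), `seeds`, `fingerprint`.
#' @export
replicate_study <- function(config = sim_config(),
                            methods = c("method1", "method2"),
                            n_reps = 20L, seed_list = NULL,
                            protocol = "fixed_features",
                            max_features = 9L, max_factors = 10L,
                            factor_band = 8:10, prescreen = Inf) {
  bad <- setdiff(methods, c("method1", "method2"))
  if (length(bad) > 0)
    stop(sprintf("unknown method name(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  if (length(methods) == 0) stop("no methods requested", call. = FALSE)
  if (is.null(seed_list)) {
    if (!is.numeric(n_reps) || n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
    seed_list <- seq_len(n_reps)
  }
  metrics <- do.call(rbind, lapply(seed_list, function(s) {
    run_methods_once(config, s, methods, protocol, max_features,
                     max_factors, prescreen)
  }))

  summ <- list()
  if ("method1" %in% methods) {
    m1 <- metrics[metrics$method == "method1", ]
    summ[[length(summ) + 1L]] <- data.frame(
      method = "method1",
      median_sensitivity = median(m1$loo_sensitivity),
      min_sensitivity = min(m1$loo_sensitivity),
      max_sensitivity = max(m1$loo_sensitivity),
      median_specificity = median(m1$loo_specificity),
      min_specificity = min(m1$loo_specificity),
      max_specificity = max(m1$loo_specificity))
  }
  if ("method2" %in% methods) {
    m2 <- metrics[metrics$method == "method2" &
                    metrics$n_factors %in% factor_band, ]
    best <- do.call(rbind, lapply(split(m2, m2$seed), function(d) {
      d[which.max(d$loo_specificity), ]
    }))
    summ[[length(summ) + 1L]] <- data.frame(
      method = "method2",
      median_sensitivity = median(best$loo_sensitivity),
      min_sensitivity = min(best$loo_sensitivity),
      max_sensitivity = max(best$loo_sensitivity),
      median_specificity = median(best$loo_specificity),
      min_specificity = min(best$loo_specificity),
      max_specificity = max(best$loo_specificity))
  }
  structure(list(metrics = metrics, summary = do.call(rbind, summ),
                 seeds = seed_list, methods = methods,
                 protocol = protocol, factor_band = factor_band,
                 fingerprint = config_fingerprint(config)),
            class = "replicate_summary")
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf("Replicate simulation study: %d seed(s), methods %s (config %s)\n",
              length(x$seeds), paste(x$methods, collapse = " + "),
              x$fingerprint))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Robustness of classification accuracy to retention-time jitter
#'
#' Reruns the replicate study at each jitter level with every other generator
#' parameter fixed, reporting the median LOO accuracy, sensitivity and
#' specificity per level. Operationalizes the claim that ~1% retention-time
#' variability leaves predictive accuracy essentially unchanged, while gross
#' jitter degrades it.
#'
#' @param config base [sim_config()].
#' @param jitter_levels non-negative jitter fractions to test.
#' @param n_reps replicates per level.
#' @param methods methods to run (default method 1 only).
#' @param ... passed to [replicate_study()].
#' @return data.frame with one row per jitter level: `jitter`,
#'   `median_accuracy`, `median_sensitivity`, `median_specificity`.
#' @export
jitter_robustness <- function(config = sim_config(), jitter_levels,
                              n_reps = 5L, methods = "method1", ...) {
  if (any(!is.finite(jitter_levels)) || any(jitter_levels < 0))
    stop("jitter levels must be >= 0", call. = FALSE)
  rows <- lapply(jitter_levels, function(j) {
    cfg <- config
    cfg$rt_jitter_frac <- j
    rs <- replicate_study(cfg, methods = methods, n_reps = n_reps, ...)
    m <- rs$metrics[rs$metrics$method == methods[1], ]
    if (methods[1] == "method2") m <- m[m$n_factors %in% rs$factor_band, ]
    data.frame(jitter = j,
               median_accuracy = median(m$loo_accuracy),
               median_sensitivity = median(m$loo_sensitivity),
               median_specificity = median(m$loo_specificity))
  })
  do.call(rbind, rows)
}
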