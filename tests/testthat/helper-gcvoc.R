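## Reduced-size simulation used where a test needs a realistic cohort but not
## the full 5040-point instrument grid: 26 samples on a 1200-point grid with a
## marker peak at index 800 (window 700-900) and three group-differential
## amplitude shifts.
small_sim_config <- function(seed = 1, ...) {
  sp <- data.frame(location = c(60, 110, 180, 320, 520, 1000),
                   width_sd = c(10, 10, 12, 14, 16, 20),
                   amplitude_mean = c(4, 3, 4.5, 3.5, 3, 3),
                   amplitude_cv = 0.15)
  se <- data.frame(location = c(60, 180, 320),
                   amplitude_shift = c(2, -1.5, 1.8))
  sim_config(n_cancer = 10, n_control = 16, grid_length = 1200,
             shared_peaks = sp, secondary_effects = se,
             marker_peak = list(location = 800, width_sd = 18,
                                amplitude_mean = 6, amplitude_cv = 0.2,
                                prevalence_cancer = 0.8,
                                prevalence_control = 0),
             seed = seed, ...)
}

## Full-size configuration with every group effect switched off: no marker
## peak, no secondary amplitude shifts. Group labels carry no signal.
null_sim_config <- function(seed = 1) {
  se <- default_secondary_effects()
  se$amplitude_shift[] <- 0
  sim_config(secondary_effects = se,
             marker_peak = list(location = 3204, width_sd = 40,
                                amplitude_mean = 0, amplitude_cv = 0.2,
                                prevalence_cancer = 0, prevalence_control = 0),
             seed = seed)
}

## Memoised default-configuration cohorts so several tests can share one
## full-size generation.
.cohort_cache <- new.env(parent = emptyenv())
default_cohort <- function(seed = 1) {
  key <- paste0("seed", seed)
  if (is.null(.cohort_cache[[key]]))
    .cohort_cache[[key]] <- simulate_cohort(sim_config(seed = seed))
  .cohort_cache[[key]]
}

## Tiny linearly separable cohort: cancers peak at t = 3/4, controls at
## t = 8/9, no noise beyond a gentle ramp keeping traces non-constant.
toy_cohort <- function() {
  tr <- function(bump_at) {
    x <- rep(10, 12)
    x[bump_at] <- 14
    x + seq(0.01, 0.12, by = 0.01)
  }
  new_cohort(rbind(tr(3), tr(4), tr(8), tr(9)),
             data.frame(sample_id = paste0("s", 1:4),
                        group = c("cancer", "cancer", "control", "control"),
                        run_index = 1:4))
}

## Single-feature Wilks' lambda by direct group sum-of-squares computation
## (independent of the package's incremental scan).
wilks_scan <- function(X, y) {
  vapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    e <- sum(tapply(x, y, function(v) sum((v - mean(v))^2)))
    e / sum((x - mean(x))^2)
  }, numeric(1))
}
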