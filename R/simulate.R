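#' Default shared peak library
#'
#' Peaks common to both diagnostic groups, spanning the elution range of the
#' 42-minute run (grid of half-second points). Widths grow with retention time:
#' the Gaussian sd runs from ~20 half-seconds at early retention to ~50 at the
#' end of the run, i.e. full peak widths of roughly 100 half-seconds on average
#' and up to ~200 at high retention times. Amplitudes are in raw sensor-response
#' units above baseline.
#'
#' @param grid_length number of half-second points per chromatogram.
#' @return a data.frame with columns `location`, `width_sd`, `amplitude_mean`,
#'   `amplitude_cv`.
#' @export
default_shared_peaks <- function(grid_length = 5040) {
  location <- c(117, 153, 174, 201, 359, 520, 760, 1073, 1162, 1362,
                1650, 2050, 2450, 2800, 3600, 4150, 4700)
  amplitude_mean <- c(5.0, 3.5, 3.0, 4.0, 4.5, 2.5, 3.0, 4.0, 3.5, 4.5,
                      2.0, 3.0, 2.5, 3.5, 3.0, 2.0, 2.5)
  data.frame(
    location = location,
    width_sd = 20 + 30 * location / grid_length,
    amplitude_mean = amplitude_mean,
    amplitude_cv = 0.15
  )
}

#' Default group-differential amplitude shifts
#'
#' Weak between-group effects at the eight early/mid-retention time points that,
#' together with the late cancer-marker peak, drive the class separation in the
#' default simulated cohorts. Each entry shifts the mean amplitude of the shared
#' peak at `location` for the cancer group by `amplitude_shift` raw units (the
#' shifts are amplitude changes of existing peaks, not new peaks). The
#' magnitudes are calibration constants of the disease model: they are chosen so
#' the end-to-end classifiers reach the cross-validated error rates the
#' instrument study reported (see the methods vignette).
#'
#' @return a data.frame with columns `location`, `amplitude_shift`.
#' @export
default_secondary_effects <- function() {
  data.frame(
    location = c(117, 153, 174, 201, 359, 1073, 1162, 1362),
    amplitude_shift = c(2.5, -1.8, 1.9, -1.5, 2.2, 1.65, -1.9, 2.05)
  )
}

#' Simulation configuration for synthetic chromatogram cohorts
#'
#' Full parameterization of the simulated instrument and disease model:
#' a two-group cohort of resistance-response chromatograms on a fixed
#' half-second grid, with Gaussian peaks, per-run multiplicative retention-time
#' jitter, per-run baseline level drift plus a gentle within-run linear slope,
#' additive measurement noise, and a daily ethanol calibration model.
#'
#' Defaults describe the study conditions: 24 cancer and 74 control samples on
#' a 5040-point grid (0.5 s sampling, 42 min), a cancer-marker peak at index
#' 3204 carried by exactly `round(20/24 * 24) = 20` of the cancer samples and
#' absent from controls, eight weaker group-differential amplitude shifts,
#' ±1% retention-time jitter, and ethanol calibration with mean retention
#' 329.2 half-seconds (SD 3.97) and mean sensitivity 98.5% (SD 10.6).
#'
#' Traces are emitted as already-inverted "response" signals: the physical
#' sensor responds with a resistance *drop*, and plotted chromatograms show the
#' drop as a positive peak, so peaks here are maxima on a positive baseline.
#'
#' @param n_cancer,n_control group sizes.
#' @param grid_length points per chromatogram.
#' @param sampling_interval seconds per grid point.
#' @param shared_peaks data.frame of peaks common to both groups
#'   (columns `location`, `width_sd`, `amplitude_mean`, `amplitude_cv`).
#' @param marker_peak list describing the cancer-marker peak: `location`,
#'   `width_sd`, `amplitude_mean`, `amplitude_cv`, `prevalence_cancer`,
#'   `prevalence_control`.
#' @param secondary_effects data.frame of group-differential amplitude shifts
#'   (columns `location`, `amplitude_shift`); every location must match a
#'   shared peak.
#' @param rt_jitter_frac multiplicative retention-time jitter per run; one
#'   factor drawn uniformly on `[1 - j, 1 + j]` per run shifts every peak
#'   center in that run.
#' @param baseline list with `start_level` (raw response units), `drift_sd`
#'   (SD of the per-run random baseline level) and `slope_sd` (SD of the
#'   within-run linear slope, units per grid step).
#' @param noise_sd SD of the additive white measurement noise (raw units).
#' @param ethanol_rt_mean,ethanol_rt_sd mean and SD (half-seconds) of the
#'   ethanol calibration peak's retention time.
#' @param sensitivity_mean,sensitivity_sd mean and SD (%) of the daily sensor
#'   sensitivity to the ethanol standard.
#' @param seed integer seed governing all randomness of the generator.
#' @return an object of class `sim_config`.
#' @seealso [simulate_cohort()], [simulate_calibration_series()]
#' @export
sim_config <- function(n_cancer = 24L,
                       n_control = 74L,
                       grid_length = 5040L,
                       sampling_interval = 0.5,
                       shared_peaks = default_shared_peaks(grid_length),
                       marker_peak = list(location = 3204, width_sd = 40,
                                          amplitude_mean = 6, amplitude_cv = 0.2,
                                          prevalence_cancer = 20 / 24,
                                          prevalence_control = 0),
                       secondary_effects = default_secondary_effects(),
                       rt_jitter_frac = 0.01,
                       baseline = list(start_level = 20, drift_sd = 2,
                                       slope_sd = 3e-4),
                       noise_sd = 0.15,
                       ethanol_rt_mean = 329.2,
                       ethanol_rt_sd = 3.97,
                       sensitivity_mean = 98.5,
                       sensitivity_sd = 10.6,
                       seed = 1L) {
  cfg <- structure(list(
    n_cancer = as.integer(n_cancer), n_control = as.integer(n_control),
    grid_length = as.integer(grid_length),
    sampling_interval = sampling_interval,
    shared_peaks = shared_peaks, marker_peak = marker_peak,
    secondary_effects = secondary_effects,
    rt_jitter_frac = rt_jitter_frac, baseline = baseline, noise_sd = noise_sd,
    ethanol_rt_mean = ethanol_rt_mean, ethanol_rt_sd = ethanol_rt_sd,
    sensitivity_mean = sensitivity_mean, sensitivity_sd = sensitivity_sd,
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks all structural invariants of a [sim_config()] object and fails with
#' an error naming the offending field.
#'
#' @param config a `sim_config` object.
#' @return `config`, invisibly, if valid.
#' @export
validate_sim_config <- function(config) {
  if (!is.list(config)) stop("config must be a sim_config list", call. = FALSE)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!num1(config$n_cancer) || config$n_cancer <= 0)
    stop_field("n_cancer", "must be a positive count")
  if (!num1(config$n_control) || config$n_control <= 0)
    stop_field("n_control", "must be a positive count")
  if (!num1(config$grid_length) || config$grid_length < 2)
    stop_field("grid_length", "must be a count >= 2")
  if (!num1(config$sampling_interval) || config$sampling_interval <= 0)
    stop_field("sampling_interval", "must be positive")
  sp <- config$shared_peaks
  if (!is.data.frame(sp) ||
      !all(c("location", "width_sd", "amplitude_mean", "amplitude_cv") %in% names(sp)))
    stop_field("shared_peaks", "must be a data.frame with columns location, width_sd, amplitude_mean, amplitude_cv")
  if (any(sp$location < 1 | sp$location > config$grid_length))
    stop_field("shared_peaks", "has a peak location outside [1, grid_length]")
  if (any(sp$width_sd <= 0)) stop_field("shared_peaks", "has a non-positive width_sd")
  if (any(sp$amplitude_mean < 0)) stop_field("shared_peaks", "has a negative amplitude_mean")
  mp <- config$marker_peak
  for (f in c("location", "width_sd", "amplitude_mean", "amplitude_cv",
              "prevalence_cancer", "prevalence_control"))
    if (!num1(mp[[f]])) stop_field(paste0("marker_peak.", f), "must be a finite number")
  if (mp$location < 1 || mp$location > config$grid_length)
    stop_field("marker_peak.location", "must lie inside [1, grid_length]")
  if (mp$width_sd <= 0) stop_field("marker_peak.width_sd", "must be positive")
  if (mp$prevalence_cancer < 0 || mp$prevalence_cancer > 1)
    stop_field("marker_peak.prevalence_cancer", "must lie in [0, 1]")
  if (mp$prevalence_control < 0 || mp$prevalence_control > 1)
    stop_field("marker_peak.prevalence_control", "must lie in [0, 1]")
  se <- config$secondary_effects
  if (!is.data.frame(se) || !all(c("location", "amplitude_shift") %in% names(se)))
    stop_field("secondary_effects", "must be a data.frame with columns location, amplitude_shift")
  if (nrow(se) > 0 && !all(se$location %in% sp$location))
    stop_field("secondary_effects", "has a location with no matching shared peak (shifts modify existing peak amplitudes)")
  if (!num1(config$rt_jitter_frac) || config$rt_jitter_frac < 0)
    stop_field("rt_jitter_frac", "must be >= 0")
  bl <- config$baseline
  if (!is.list(bl) || !all(c("start_level", "drift_sd", "slope_sd") %in% names(bl)))
    stop_field("baseline", "must be a list with start_level, drift_sd, slope_sd")
  if (!num1(bl$start_level) || bl$start_level <= 0)
    stop_field("baseline.start_level", "must be positive")
  if (!num1(bl$drift_sd) || bl$drift_sd < 0) stop_field("baseline.drift_sd", "must be >= 0")
  if (!num1(bl$slope_sd) || bl$slope_sd < 0) stop_field("baseline.slope_sd", "must be >= 0")
  if (!num1(config$noise_sd) || config$noise_sd < 0) stop_field("noise_sd", "must be >= 0")
  if (!num1(config$ethanol_rt_mean) || config$ethanol_rt_mean < 1 ||
      config$ethanol_rt_mean > config$grid_length)
    stop_field("ethanol_rt_mean", "must lie inside the grid")
  if (!num1(config$ethanol_rt_sd) || config$ethanol_rt_sd < 0)
    stop_field("ethanol_rt_sd", "must be >= 0")
  if (!num1(config$sensitivity_mean)) stop_field("sensitivity_mean", "must be a finite number")
  if (!num1(config$sensitivity_sd) || config$sensitivity_sd < 0)
    stop_field("sensitivity_sd", "must be >= 0")
  if (!num1(config$seed)) stop_field("seed", "must be an integer")
  invisible(config)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration (sim_config)\n")
  cat(sprintf("  cohort: %d cancer + %d control on a %d-point grid (%.1f s/point)\n",
              x$n_cancer, x$n_control, x$grid_length, x$sampling_interval))
  cat(sprintf("  shared peaks: %d; marker peak at %g (prevalence %.3f cancer / %.3f control)\n",
              nrow(x$shared_peaks), x$marker_peak$location,
              x$marker_peak$prevalence_cancer, x$marker_peak$prevalence_control))
  cat(sprintf("  secondary amplitude shifts at: %s\n",
              paste(x$secondary_effects$location, collapse = ", ")))
  cat(sprintf("  rt jitter +/-%.1f%%, baseline %g (drift sd %g, slope sd %g), noise sd %g\n",
              100 * x$rt_jitter_frac, x$baseline$start_level, x$baseline$drift_sd,
              x$baseline$slope_sd, x$noise_sd))
  cat(sprintf("  ethanol calibration: rt %.1f (sd %.2f), sensitivity %.1f%% (sd %.1f)\n",
              x$ethanol_rt_mean, x$ethanol_rt_sd, x$sensitivity_mean, x$sensitivity_sd))
  cat(sprintf("  seed %d   fingerprint %s\n", x$seed, config_fingerprint(x)))
  invisible(x)
}

#' Render a single Gaussian chromatographic peak
#'
#' Evaluates a Gaussian peak of the given apex amplitude on the half-second
#' index grid `1..grid_length`. For an integer `location` the rendered maximum
#' sits exactly at that index with value `amplitude`; for a fractional location
#' the apex falls on the nearest grid point.
#'
#' @param location peak center, half-second index (may be fractional).
#' @param width_sd Gaussian sd in half-seconds; the full width at 10% of
#'   maximum is `2 * width_sd * sqrt(2 * log(10))` grid points.
#' @param amplitude apex height in raw response units; zero gives a flat
#'   all-zero signal.
#' @param grid_length number of grid points.
#' @return numeric vector of length `grid_length`.
#' @examples
#' sig <- render_peak(3204, 25, 1, 5040)
#' which.max(sig)  # 3204
#' @export
render_peak <- function(location, width_sd, amplitude, grid_length) {
  if (!is.numeric(grid_length) || length(grid_length) != 1L || grid_length < 1)
    stop("grid_length must be a positive count", call. = FALSE)
  if (!is.numeric(location) || length(location) != 1L ||
      location < 1 || location > grid_length)
    stop("location must lie inside [1, grid_length]", call. = FALSE)
  if (!is.numeric(width_sd) || length(width_sd) != 1L || width_sd <= 0)
    stop("width_sd must be positive", call. = FALSE)
  if (!is.numeric(amplitude) || length(amplitude) != 1L || amplitude < 0)
    stop("amplitude must be non-negative", call. = FALSE)
  if (amplitude == 0) return(numeric(grid_length))
  t <- seq_len(grid_length)
  amplitude * exp(-0.5 * ((t - location) / width_sd)^2)
}

## Gaussian signal without the center-in-grid restriction of render_peak():
## under large retention-time jitter a peak center can be displaced beyond the
## end of the run, in which case only its tail is recorded.
gauss_signal <- function(center, width_sd, amplitude, grid_length) {
  if (amplitude == 0) return(numeric(grid_length))
  t <- seq_len(grid_length)
  amplitude * exp(-0.5 * ((t - center) / width_sd)^2)
}

## Draw per-sample peak amplitudes: normal around the (possibly group-shifted)
## mean with sd = cv * base mean, floored at 5% of the base mean so a rare far
## tail draw cannot produce a negative or vanishing peak.
draw_amplitudes <- function(mean, cv, n) {
  pmax(rnorm(n, mean, cv * mean), 0.05 * mean)
}

#' Simulate a two-group chromatogram cohort
#'
#' Generates `n_cancer + n_control` resistance-response chromatograms under the
#' instrument/disease model of a [sim_config()]: each sample is one run, with a
#' per-run baseline level, a gentle within-run linear slope, one multiplicative
#' retention-time jitter factor applied to every peak center in the run,
#' Gaussian shared peaks with random amplitudes, group-differential amplitude
#' shifts for the cancer group, the cancer-marker peak assigned without
#' replacement to exactly `round(prevalence_cancer * n_cancer)` cancer samples
#' (and `round(prevalence_control * n_control)` controls), and additive white
#' noise. Identical seeds give bit-identical cohorts.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `cohort`: a list with the raw `n x grid_length`
#'   response matrix `X`, a `meta` data.frame (`sample_id`, `group`,
#'   `run_index`), the generating `config`, and a `truth` list holding the
#'   generator's ground truth (marker assignment, jitter factors, baseline
#'   levels, slopes, per-peak amplitudes).
#' @seealso [cohort_matrix()], [read_cohort()], [write_cohort()]
#' @export
simulate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  with_seed(config$seed, {
    n1 <- config$n_cancer; n0 <- config$n_control; n <- n1 + n0
    G <- config$grid_length
    group <- c(rep("cancer", n1), rep("control", n0))
    sample_id <- c(sprintf("ca%03d", seq_len(n1)), sprintf("ct%03d", seq_len(n0)))

    ## samples are run in a random interleaved date order
    run_index <- sample.int(n)
    level_by_run <- config$baseline$start_level + rnorm(n, 0, config$baseline$drift_sd)
    baseline_level <- level_by_run[run_index]
    slope <- rnorm(n, 0, config$baseline$slope_sd)
    j <- config$rt_jitter_frac
    jitter_factor <- if (j > 0) runif(n, 1 - j, 1 + j) else rep(1, n)

    ## deterministic marker assignment: exactly round(prevalence * n) carriers
    k1 <- round(config$marker_peak$prevalence_cancer * n1)
    k0 <- round(config$marker_peak$prevalence_control * n0)
    marker_carrier <- logical(n)
    marker_carrier[sample(which(group == "cancer"), k1)] <- TRUE
    if (k0 > 0) marker_carrier[sample(which(group == "control"), k0)] <- TRUE

    sp <- config$shared_peaks
    npk <- nrow(sp)
    shift <- numeric(npk)
    m <- match(config$secondary_effects$location, sp$location)
    shift[m] <- config$secondary_effects$amplitude_shift

    amplitudes <- matrix(0, n, npk)
    for (k in seq_len(npk)) {
      mu <- sp$amplitude_mean[k] + ifelse(group == "cancer", shift[k], 0)
      amplitudes[, k] <- draw_amplitudes(mu, sp$amplitude_cv[k], n)
    }
    mp <- config$marker_peak
    marker_amplitude <- ifelse(
      marker_carrier, draw_amplitudes(mp$amplitude_mean, mp$amplitude_cv, n), 0)

    X <- matrix(0, n, G)
    tg <- seq_len(G) - 1
    for (i in seq_len(n)) {
      trace <- baseline_level[i] + slope[i] * tg
      for (k in seq_len(npk)) {
        trace <- trace + gauss_signal(jitter_factor[i] * sp$location[k],
                                      sp$width_sd[k], amplitudes[i, k], G)
      }
      if (marker_carrier[i]) {
        trace <- trace + gauss_signal(jitter_factor[i] * mp$location,
                                      mp$width_sd, marker_amplitude[i], G)
      }
      X[i, ] <- trace
    }
    if (config$noise_sd > 0)
      X <- X + matrix(rnorm(n * G, 0, config$noise_sd), n, G)

    new_cohort(
      X = X,
      meta = data.frame(sample_id = sample_id, group = group,
                        run_index = run_index, stringsAsFactors = FALSE),
      config = config,
      truth = list(marker_carrier = marker_carrier,
                   marker_amplitude = marker_amplitude,
                   jitter_factor = jitter_factor,
                   baseline_level = baseline_level, slope = slope,
                   amplitudes = amplitudes)
    )
  })
}

#' Construct a chromatogram cohort object
#'
#' @param X numeric `n x grid_length` matrix of raw response traces
#'   (positive, finite).
#' @param meta data.frame with columns `sample_id`, `group`
#'   (in `{cancer, control}`), `run_index`.
#' @param config optional generating [sim_config()].
#' @param truth optional generator ground truth.
#' @return an object of class `cohort`.
#' @export
new_cohort <- function(X, meta, config = NULL, truth = NULL) {
  X <- as.matrix(X)
  if (nrow(X) != nrow(meta)) stop("X and meta disagree on sample count", call. = FALSE)
  if (!all(c("sample_id", "group", "run_index") %in% names(meta)))
    stop("meta must have columns sample_id, group, run_index", call. = FALSE)
  bad <- setdiff(unique(meta$group), c("cancer", "control"))
  if (length(bad) > 0)
    stop(sprintf("unknown group label(s): %s", paste(bad, collapse = ", ")), call. = FALSE)
  if (anyDuplicated(meta$sample_id))
    stop(sprintf("duplicated sample_id: %s",
                 meta$sample_id[anyDuplicated(meta$sample_id)]), call. = FALSE)
  if (!all(is.finite(X))) stop("traces contain non-finite values", call. = FALSE)
  if (any(X <= 0)) stop("raw resistance traces must be positive", call. = FALSE)
  structure(list(X = X, meta = meta, config = config, truth = truth),
            class = "cohort")
}

is_cohort <- function(x) inherits(x, "cohort")

#' @export
print.cohort <- function(x, ...) {
  tb <- table(x$meta$group)
  cat(sprintf("Chromatogram cohort: %d samples (%s) on a %d-point grid\n",
              nrow(x$X),
              paste(sprintf("%d %s", tb, names(tb)), collapse = ", "),
              ncol(x$X)))
  if (!is.null(x$config))
    cat(sprintf("  generated from sim_config seed %d (fingerprint %s)\n",
                x$config$seed, config_fingerprint(x$config)))
  invisible(x)
}

#' Feature-matrix view of a cohort
#'
#' @param cohort a `cohort` object.
#' @param standardize if `TRUE`, each row (profile) is standardized to mean 0
#'   and sample sd 1 (the within-profile transform applied before all
#'   modelling).
#' @return numeric `n x grid_length` matrix with rownames `sample_id`.
#' @export
cohort_matrix <- function(cohort, standardize = FALSE) {
  stopifnot(is_cohort(cohort))
  X <- cohort$X
  if (standardize) {
    mu <- rowMeans(X)
    s <- sqrt(rowSums((X - mu)^2) / (ncol(X) - 1))
    if (any(s < 1e-12)) stop("cohort contains a constant trace", call. = FALSE)
    X <- (X - mu) / s
  }
  rownames(X) <- cohort$meta$sample_id
  X
}

#' Group labels of a cohort as a factor
#'
#' @param cohort a `cohort` object.
#' @return factor with levels `cancer`, `control`.
#' @export
cohort_labels <- function(cohort) {
  factor(cohort$meta$group, levels = c("cancer", "control"))
}

#' Simulate a daily ethanol calibration series
#'
#' Emulates the daily single-compound calibration of the sensor against a
#' certified ethanol gas standard. For each day a true retention time is drawn
#' around `ethanol_rt_mean` (SD `ethanol_rt_sd`), an ethanol response trace is
#' rendered on the instrument grid with additive noise, and the retention time
#' is *recovered by peak detection* on that trace. The daily sensitivity is
#' drawn around `sensitivity_mean` (SD `sensitivity_sd`, truncated to the
#' physical range of a resistance-drop sensor) and expressed as the
#' baseline/exposed resistance pair `(r0, rg)` with
#' `sensitivity = 100 * (r0 - rg) / r0`.
#'
#' @param config a [sim_config()] object.
#' @param n_days number of daily runs (>= 1).
#' @return a data.frame of class `calibration_series` with columns
#'   `day_index`, `detected_rt`, `r0`, `rg`; the drawn true retention times are
#'   attached as attribute `true_rt`.
#' @seealso [sensor_sensitivity()], [detect_peak()]
#' @export
simulate_calibration_series <- function(config = sim_config(), n_days) {
  validate_sim_config(config)
  if (!is.numeric(n_days) || length(n_days) != 1L || n_days < 1)
    stop("n_days must be >= 1", call. = FALSE)
  n_days <- as.integer(n_days)
  with_seed(config$seed, {
    G <- config$grid_length
    sigma_e <- 20 + 30 * config$ethanol_rt_mean / G
    rt_true <- rnorm(n_days, config$ethanol_rt_mean, config$ethanol_rt_sd)
    rt_true <- pmin(pmax(rt_true, 1 + 3 * sigma_e), G - 3 * sigma_e)
    sens <- rnorm(n_days, config$sensitivity_mean, config$sensitivity_sd)
    sens <- pmin(pmax(sens, 0.1), 99.9)
    r0 <- 10 * (config$baseline$start_level +
                  rnorm(n_days, 0, config$baseline$drift_sd))
    r0 <- pmax(r0, 1)
    rg <- r0 * (1 - sens / 100)
    amp <- 5
    win <- c(max(2, round(config$ethanol_rt_mean - 6 * sigma_e)),
             min(G - 1, round(config$ethanol_rt_mean + 6 * sigma_e)))
    detected_rt <- integer(n_days)
    for (d in seq_len(n_days)) {
      trace <- render_peak(rt_true[d], sigma_e, amp, G)
      if (config$noise_sd > 0) trace <- trace + rnorm(G, 0, config$noise_sd)
      pk <- detect_peak(trace, window = win, min_height = amp / 2)
      detected_rt[d] <- if (pk$measurable) pk$location else round(rt_true[d])
    }
    out <- data.frame(day_index = seq_len(n_days), detected_rt = detected_rt,
                      r0 = r0, rg = rg)
    attr(out, "true_rt") <- rt_true
    class(out) <- c("calibration_series", "data.frame")
    out
  })
}
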