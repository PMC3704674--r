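#' Standardize a resistance profile
#'
#' Rescales one chromatogram to mean 0 and sample standard deviation 1
#' (denominator `n - 1`). The transform puts every donor profile on the same
#' scale so groups can be compared free of baseline-level and gain effects,
#' while preserving the relative minima and maxima within each profile: it is
#' invariant under any positive affine map `a * x + b` of the raw trace.
#'
#' @param x numeric vector (one raw trace) with at least 2 distinct values.
#' @return numeric vector of the same length with mean 0 and sample sd 1.
#' @examples
#' standardize(c(1, 2, 3))  # -1 0 1
#' @export
standardize <- function(x) {
  if (!is.numeric(x) || length(x) < 2)
    stop("profile must be a numeric vector of length >= 2", call. = FALSE)
  if (!all(is.finite(x))) stop("profile contains non-finite values", call. = FALSE)
  s <- sd(x)
  if (!is.finite(s) || s < 1e-12)
    stop("degenerate input: constant trace has zero variance", call. = FALSE)
  (x - mean(x)) / s
}

#' Group-average standardized chromatogram
#'
#' Pointwise arithmetic mean of the standardized profiles of one diagnostic
#' group, as used to overlay the group-average chromatograms.
#'
#' @param cohort a `cohort` object.
#' @param group `"cancer"` or `"control"` (must be present in the cohort).
#' @return numeric vector of length `grid_length`.
#' @export
group_mean_profile <- function(cohort, group) {
  stopifnot(is_cohort(cohort))
  if (!group %in% cohort$meta$group)
    stop(sprintf("unknown or empty group label: '%s'", group), call. = FALSE)
  Z <- cohort_matrix(cohort, standardize = TRUE)
  colMeans(Z[cohort$meta$group == group, , drop = FALSE])
}

#' Default measurability threshold for peak detection
#'
#' A robust signal-over-noise convention: three times a robust noise scale,
#' taken as the median absolute deviation of the first differences of the
#' profile.
#'
#' @param values numeric profile.
#' @return non-negative scalar threshold.
#' @export
default_min_height <- function(values) {
  3 * mad(diff(values))
}

#' Detect a measurable peak in a window
#'
#' Scans an index window for local maxima and reports the highest one. The
#' peak is called *measurable* when its apex exceeds the local baseline level
#' (the median of the window) by at least `min_height`.
#'
#' @param values numeric profile (typically a standardized trace).
#' @param window length-2 integer vector `(lo, hi)`, a non-empty index
#'   interval inside the grid.
#' @param min_height non-negative height threshold; defaults to
#'   [default_min_height()] of the profile.
#' @return an object of class `peak_call`: list with `location` (apex index or
#'   `NA`), `height` (apex minus window median), `window`, `min_height` and
#'   logical `measurable`.
#' @export
detect_peak <- function(values, window, min_height = NULL) {
  if (!is.numeric(values) || length(values) < 3)
    stop("profile must be a numeric vector of length >= 3", call. = FALSE)
  if (length(window) != 2L || any(!is.finite(window)))
    stop("window must be a finite (lo, hi) pair", call. = FALSE)
  lo <- as.integer(window[1]); hi <- as.integer(window[2])
  if (lo > hi) stop("empty window: lo > hi", call. = FALSE)
  if (lo < 1 || hi > length(values))
    stop("window must lie inside the grid", call. = FALSE)
  if (is.null(min_height)) min_height <- default_min_height(values)
  if (!is.numeric(min_height) || min_height < 0)
    stop("min_height must be >= 0", call. = FALSE)

  idx <- lo:hi
  ## neighbor values, treating off-grid neighbors as -Inf
  vl <- ifelse(idx - 1L >= 1L, values[pmax(idx - 1L, 1L)], -Inf)
  vr <- ifelse(idx + 1L <= length(values), values[pmin(idx + 1L, length(values))], -Inf)
  v <- values[idx]
  is_max <- v > vl & v >= vr
  base <- median(v)
  out <- list(location = NA_integer_, height = NA_real_,
              window = c(lo, hi), min_height = min_height, measurable = FALSE)
  if (any(is_max)) {
    cand <- idx[is_max]
    apex <- cand[which.max(values[cand])]
    h <- values[apex] - base
    out$location <- apex
    out$height <- h
    out$measurable <- h >= min_height && h > 0
  }
  class(out) <- "peak_call"
  out
}

#' @export
print.peak_call <- function(x, ...) {
  if (x$measurable) {
    cat(sprintf("Peak call: measurable peak at index %d (height %.3f over window [%d, %d] baseline)\n",
                x$location, x$height, x$window[1], x$window[2]))
  } else {
    cat(sprintf("Peak call: no measurable peak in window [%d, %d] (threshold %.3f)\n",
                x$window[1], x$window[2], x$min_height))
  }
  invisible(x)
}

#' Retention-time stability summary
#'
#' Summarizes tracked peak locations across runs: per-peak mean, standard
#' deviation, and maximum fractional deviation `max|x - mean| / mean`, the
#' quantity used to check that day-to-day retention-time fluctuation stays
#' within about +/-1%.
#'
#' @param peak_tracks a non-empty numeric vector (one track) or a named list
#'   of such vectors (one per tracked peak).
#' @return data.frame with columns `peak`, `n_runs`, `mean`, `sd`,
#'   `max_frac_dev`.
#' @export
assess_rt_stability <- function(peak_tracks) {
  if (is.numeric(peak_tracks)) peak_tracks <- list(peak1 = peak_tracks)
  if (!is.list(peak_tracks) || length(peak_tracks) == 0)
    stop("peak_tracks must be a numeric vector or non-empty list", call. = FALSE)
  nm <- names(peak_tracks) %||% paste0("peak", seq_along(peak_tracks))
  rows <- lapply(seq_along(peak_tracks), function(k) {
    x <- peak_tracks[[k]]
    if (!is.numeric(x) || length(x) == 0)
      stop(sprintf("track '%s' is empty or non-numeric", nm[k]), call. = FALSE)
    if (!all(is.finite(x)))
      stop(sprintf("track '%s' contains non-finite entries", nm[k]), call. = FALSE)
    m <- mean(x)
    data.frame(peak = nm[k], n_runs = length(x), mean = m,
               sd = if (length(x) > 1) sd(x) else 0,
               max_frac_dev = max(abs(x - m)) / m)
  })
  do.call(rbind, rows)
}

#' Sensor sensitivity to a calibration gas
#'
#' Percentage resistance drop of the metal-oxide sensor on exposure:
#' `100 * (r0 - rg) / r0`, where `r0` is the baseline resistance and `rg` the
#' resistance when exposed to the ethanol standard.
#'
#' @param r0 baseline resistance(s), > 0.
#' @param rg exposed resistance(s), >= 0.
#' @return sensitivity in percent (vectorized).
#' @examples
#' sensor_sensitivity(200, 3)  # 98.5
#' @export
sensor_sensitivity <- function(r0, rg) {
  if (!is.numeric(r0) || any(!is.finite(r0)) || any(r0 <= 0))
    stop("r0 must be positive", call. = FALSE)
  if (!is.numeric(rg) || any(!is.finite(rg)) || any(rg < 0))
    stop("rg must be non-negative", call. = FALSE)
  100 * (r0 - rg) / r0
}

#' Marker-peak calls for every sample of a cohort
#'
#' Standardizes each profile and runs [detect_peak()] over a window, returning
#' one row per sample. The default window `(3100, 3300)` brackets the
#' cancer-marker region around index 3200.
#'
#' @param cohort a `cohort` object.
#' @param window index window searched.
#' @param min_height height threshold; `NULL` for the per-profile default.
#' @return data.frame with columns `sample_id`, `group`, `measurable`,
#'   `location`, `height`.
#' @export
peak_calls <- function(cohort, window = c(3100, 3300), min_height = NULL) {
  stopifnot(is_cohort(cohort))
  Z <- cohort_matrix(cohort, standardize = TRUE)
  rows <- lapply(seq_len(nrow(Z)), function(i) {
    pk <- detect_peak(Z[i, ], window = window, min_height = min_height)
    data.frame(sample_id = cohort$meta$sample_id[i],
               group = cohort$meta$group[i],
               measurable = pk$measurable,
               location = pk$location, height = pk$height)
  })
  do.call(rbind, rows)
}
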