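test_that("standardize fixes mean 0 / sample sd 1 and is idempotent and affine-invariant", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))

  set.seed(2)
  x <- cumsum(rnorm(500)) + 50
  z <- standardize(x)
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(sd(z), 1, tolerance = 1e-10)
  expect_equal(standardize(z), z, tolerance = 1e-12)
  expect_equal(standardize(2.5 * x + 7), z, tolerance = 1e-12)
  ## order and relative extrema preserved
  expect_identical(order(z), order(x))

  expect_error(standardize(rep(4, 10)), "constant")
  expect_error(standardize(3), "length")
})

test_that("group mean profiles average standardized traces and respect group weights", {
  ## a group of one sample is that sample's standardized profile
  tr <- function(f) 10 + f * sin(seq_len(50) / 3) + seq_len(50) / 100
  coh1 <- new_cohort(rbind(tr(2), tr(5)),
                     data.frame(sample_id = c("a", "b"),
                                group = c("cancer", "control"), run_index = 1:2))
  expect_equal(group_mean_profile(coh1, "cancer"), standardize(tr(2)),
               ignore_attr = TRUE)

  ## two mirror-image standardized profiles average to zero
  x <- tr(3)
  mirror <- 2 * mean(x) - x  # standardizes to -standardize(x)
  coh2 <- new_cohort(rbind(x, mirror, tr(1)),
                     data.frame(sample_id = c("a", "b", "c"),
                                group = c("cancer", "cancer", "control"),
                                run_index = 1:3))
  expect_equal(group_mean_profile(coh2, "cancer"), rep(0, 50),
               tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(group_mean_profile(coh1, "benign"), "unknown")

  ## whole-cohort mean equals the size-weighted average of group means
  coh <- simulate_cohort(small_sim_config(seed = 4))
  Z <- cohort_matrix(coh, standardize = TRUE)
  n1 <- sum(coh$meta$group == "cancer")
  n0 <- sum(coh$meta$group == "control")
  weighted <- (n1 * group_mean_profile(coh, "cancer") +
                 n0 * group_mean_profile(coh, "control")) / (n1 + n0)
  expect_equal(colMeans(Z), weighted, tolerance = 1e-10, ignore_attr = TRUE)

  ## cancer-group mean exceeds the control mean over the marker window
  cohd <- default_cohort(1)
  win <- 3100:3300
  margin <- mean(group_mean_profile(cohd, "cancer")[win]) -
    mean(group_mean_profile(cohd, "control")[win])
  expect_gt(margin, 0)
})

test_that("detect_peak finds constructed peaks and rejects flat profiles", {
  expect_false(detect_peak(rep(0, 400), c(100, 300))$measurable)

  sig <- render_peak(3204, 25, 2, 5040) + 0.001 * seq_len(5040) / 5040
  pk <- detect_peak(sig, c(3100, 3300), min_height = 0.5)
  expect_true(pk$measurable)
  expect_equal(pk$location, 3204)

  expect_error(detect_peak(sig, c(3300, 3100)), "empty window")
  expect_error(detect_peak(sig, c(0, 100)), "grid")
  expect_error(detect_peak(sig, c(3100, 3300), min_height = -1), "min_height")
})

test_that("detect_peak agrees with a brute-force scan over window local maxima", {
  set.seed(11)
  for (r in 1:25) {
    v <- as.numeric(stats::filter(rnorm(300), rep(0.2, 5), sides = 2))
    v[is.na(v)] <- 0
    v <- v + seq(0, 1, length.out = 300)
    lo <- sample(5:150, 1)
    hi <- lo + sample(20:100, 1)
    mh <- runif(1, 0, 0.5)
    pk <- detect_peak(v, c(lo, hi), mh)

    cands <- integer(0)
    for (i in lo:hi) {
      vl <- if (i > 1) v[i - 1] else -Inf
      vr <- if (i < length(v)) v[i + 1] else -Inf
      if (v[i] > vl && v[i] >= vr) cands <- c(cands, i)
    }
    if (length(cands) == 0) {
      expect_false(pk$measurable)
    } else {
      apex <- cands[which.max(v[cands])]
      h <- v[apex] - median(v[lo:hi])
      expect_equal(pk$location, apex)
      expect_equal(pk$measurable, h >= mh && h > 0)
      expect_equal(pk$height, h)
    }
  }
})

test_that("marker-window peak calls recover the generator's assignment", {
  coh <- default_cohort(1)
  pc <- peak_calls(coh, window = c(3100, 3300))
  expect_equal(sum(pc$measurable[pc$group == "cancer"]),
               sum(coh$truth$marker_carrier[coh$meta$group == "cancer"]))
  ## measurable calls coincide with the true carriers sample-by-sample
  cancer <- pc$group == "cancer"
  expect_equal(pc$measurable[cancer],
               coh$truth$marker_carrier[coh$meta$group == "cancer"])
})

test_that("retention-time stability summaries compute mean, sd and fractional deviation", {
  st <- assess_rt_stability(c(500, 500, 500))
  expect_equal(st$sd, 0)
  expect_equal(st$max_frac_dev, 0)

  st2 <- assess_rt_stability(list(p = c(99, 101)))
  expect_equal(st2$mean, 100)
  expect_equal(st2$max_frac_dev, 0.01)

  expect_error(assess_rt_stability(c(100, NA)), "non-finite")

  ## under +/-1% jitter each true marker center is within 1% of its nominal
  ## location, so its deviation from the track mean is at most 2%
  coh <- default_cohort(1)
  carriers <- coh$truth$marker_carrier
  true_centers <- coh$truth$jitter_factor[carriers] * 3204
  expect_true(all(abs(true_centers - 3204) <= 0.01 * 3204 + 1e-9))
  st_true <- assess_rt_stability(list(marker = true_centers))
  expect_lte(st_true$max_frac_dev, 0.02)
  expect_lt(abs(st_true$mean - 3204), 0.01 * 3204)
  ## detected apexes track the same retention times (plus apex-location noise
  ## from the broad peak top) and stay centred on the marker
  pc <- peak_calls(coh, window = c(3100, 3300))
  locs <- pc$location[pc$measurable]
  st3 <- assess_rt_stability(list(marker = locs))
  expect_lt(abs(st3$mean - 3204), 0.01 * 3204)
})

test_that("sensor sensitivity implements the fractional resistance drop", {
  expect_equal(sensor_sensitivity(200, 3), 98.5)
  expect_equal(sensor_sensitivity(150, 150), 0)
  expect_equal(sensor_sensitivity(150, 0), 100)
  expect_equal(sensor_sensitivity(c(100, 200), c(50, 100)), c(50, 50))
  expect_error(sensor_sensitivity(0, 1), "r0")
  expect_error(sensor_sensitivity(100, -1), "rg")
})
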