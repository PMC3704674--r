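test_that("cohort generation is seed-deterministic and marker assignment is exact", {
  cfg <- small_sim_config(seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$X, b$X)
  expect_identical(a$meta, b$meta)
  expect_identical(a$truth$marker_carrier, b$truth$marker_carrier)

  coh <- default_cohort(1)
  expect_equal(sum(coh$truth$marker_carrier[coh$meta$group == "cancer"]), 20)
  expect_equal(sum(coh$truth$marker_carrier[coh$meta$group == "control"]), 0)
  expect_equal(nrow(coh$X), 98)
})

test_that("without noise, jitter or drift the cohort is exactly baseline plus rendered peaks", {
  sp <- data.frame(location = c(200, 600, 1000), width_sd = 15,
                   amplitude_mean = c(4, 3, 5), amplitude_cv = 0.2)
  cfg <- sim_config(n_cancer = 3, n_control = 3, grid_length = 1200,
                    shared_peaks = sp,
                    secondary_effects = data.frame(location = numeric(0),
                                                   amplitude_shift = numeric(0)),
                    marker_peak = list(location = 850, width_sd = 15,
                                       amplitude_mean = 5, amplitude_cv = 0.2,
                                       prevalence_cancer = 2 / 3,
                                       prevalence_control = 0),
                    rt_jitter_frac = 0, noise_sd = 0,
                    baseline = list(start_level = 20, drift_sd = 0, slope_sd = 0),
                    seed = 3)
  coh <- simulate_cohort(cfg)
  G <- cfg$grid_length
  for (i in seq_len(nrow(coh$X))) {
    expected <- rep(20, G)
    for (k in seq_len(nrow(sp))) {
      expected <- expected + render_peak(sp$location[k], sp$width_sd[k],
                                         coh$truth$amplitudes[i, k], G)
    }
    if (coh$truth$marker_carrier[i]) {
      expected <- expected + render_peak(850, 15, coh$truth$marker_amplitude[i], G)
    }
    expect_identical(coh$X[i, ], expected)
  }
  ## peaks are well separated, so every apex sits exactly at its location
  for (loc in sp$location) {
    for (i in seq_len(nrow(coh$X))) {
      win <- (loc - 60):(loc + 60)
      expect_equal(win[which.max(coh$X[i, win])], loc)
    }
  }
})

test_that("render_peak matches its Gaussian closed form", {
  expect_identical(render_peak(100, 10, 0, 500), numeric(500))

  sig <- render_peak(3204, 25, 1, 5040)
  expect_equal(which.max(sig), 3204)
  expect_equal(sig[3204], 1.0)
  expect_true(all(sig >= 0))
  ## full width at 10% of maximum: 2 * w * sqrt(2 * ln 10), within one grid step
  width10 <- sum(sig >= 0.1)
  expect_lt(abs(width10 - 2 * 25 * sqrt(2 * log(10))), 1)

  expect_error(render_peak(100, 0, 1, 500), "width_sd")
  expect_error(render_peak(100, 10, -1, 500), "amplitude")
  expect_error(render_peak(600, 10, 1, 500), "location")
})

test_that("retention-time jitter displacements are bounded by the configured fraction", {
  for (s in 1:5) {
    cfg <- small_sim_config(seed = s)
    cfg$rt_jitter_frac <- 0.02
    coh <- simulate_cohort(cfg)
    jf <- coh$truth$jitter_factor
    expect_true(all(abs(jf - 1) <= 0.02))
    ## realized center displacement of every peak obeys |d| <= j * location
    for (loc in cfg$shared_peaks$location) {
      expect_true(all(abs(jf * loc - loc) <= 0.02 * loc + 1e-12))
    }
  }
})

test_that("doubling the noise scale doubles the residual spread", {
  base <- small_sim_config(seed = 21)
  quiet <- base; quiet$noise_sd <- 0
  one <- base; one$noise_sd <- 0.2
  two <- base; two$noise_sd <- 0.4
  X0 <- simulate_cohort(quiet)$X
  r1 <- simulate_cohort(one)$X - X0
  r2 <- simulate_cohort(two)$X - X0
  expect_equal(sd(r2), 2 * sd(r1), tolerance = 1e-10)
  expect_equal(sd(r1), 0.2, tolerance = 0.01)
})

test_that("degenerate calibration distributions echo the configured constants", {
  cfg <- small_sim_config(seed = 5)
  cfg$ethanol_rt_sd <- 0
  cfg$sensitivity_sd <- 0
  cfg$noise_sd <- 0
  cfg$baseline$drift_sd <- 0
  cal <- simulate_calibration_series(cfg, 3)
  expect_equal(cal$detected_rt, rep(329L, 3))  # 329.2 rounded to the grid
  expect_equal(sensor_sensitivity(cal$r0, cal$rg), rep(98.5, 3))
})

test_that("the simulated calibration series recovers the configured retention-time mean", {
  cfg <- sim_config(seed = 1)
  cal <- simulate_calibration_series(cfg, 150)
  expect_equal(nrow(cal), 150)
  se <- cfg$ethanol_rt_sd / sqrt(150)
  expect_lt(abs(mean(cal$detected_rt) - 329.2), se)
  expect_true(all(cal$rg > 0 & cal$rg <= cal$r0))
  ## seeded determinism
  expect_identical(cal, simulate_calibration_series(cfg, 150))
  expect_error(simulate_calibration_series(cfg, 0), "n_days")
})

test_that("configuration errors name the offending field", {
  expect_error(sim_config(n_cancer = 0), "n_cancer")
  expect_error(sim_config(rt_jitter_frac = -0.1), "rt_jitter_frac")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(sim_config(marker_peak = list(location = 6000, width_sd = 40,
                                             amplitude_mean = 6, amplitude_cv = 0.2,
                                             prevalence_cancer = 0.5,
                                             prevalence_control = 0)),
               "marker_peak.location")
  expect_error(sim_config(marker_peak = list(location = 3204, width_sd = 40,
                                             amplitude_mean = 6, amplitude_cv = 0.2,
                                             prevalence_cancer = 1.5,
                                             prevalence_control = 0)),
               "prevalence_cancer")
  expect_error(sim_config(secondary_effects = data.frame(location = 999,
                                                         amplitude_shift = 1)),
               "secondary_effects")
})
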