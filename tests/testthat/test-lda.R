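test_that("one-feature discriminant puts the threshold midway between group means", {
  X <- matrix(c(1, 2, 3, -1, 0, 1), ncol = 1)
  y <- rep(c("cancer", "control"), each = 3)  # means 2 and 0, equal spread
  fit <- fisher_fit(X, y)
  expect_gt(fit$coefficients, 0)
  expect_equal(fit$threshold / fit$coefficients, 1)  # projected cut at x = 1
  expect_equal(classify(fit, 1)$label, "control")    # tie goes to control
  expect_equal(classify(fit, 1.01)$label, "cancer")
  expect_equal(classify(fit, 0.99)$label, "control")
})

test_that("with spherical within-group scatter the direction is the mean difference", {
  dev <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  X <- rbind(sweep(dev, 2, c(2, 1), "+"), dev)  # means (2,1) and (0,0)
  y <- rep(c("cancer", "control"), each = 4)
  fit <- fisher_fit(X, y)
  expect_equal(fit$coefficients[1] / fit$coefficients[2], 2 / 1, tolerance = 1e-10)
})

test_that("fitted direction matches a dense search maximizing the Fisher criterion", {
  fisher_angle_oracle <- function(X, y) {
    pos <- X[y == "cancer", , drop = FALSE]
    neg <- X[y == "control", , drop = FALSE]
    dm <- colMeans(pos) - colMeans(neg)
    Sp <- (crossprod(scale(pos, scale = FALSE)) +
             crossprod(scale(neg, scale = FALSE))) / (nrow(X) - 2)
    crit <- function(th) {
      W <- rbind(cos(th), sin(th))
      as.vector((dm %*% W)^2 / colSums(W * (Sp %*% W)))
    }
    th <- seq(0, pi, length.out = 20001)
    th0 <- th[which.max(crit(th))]
    th2 <- seq(th0 - 2e-4, th0 + 2e-4, length.out = 40001)
    th2[which.max(crit(th2))]
  }
  set.seed(31)
  for (r in 1:5) {
    X <- matrix(rnorm(12), 6, 2)
    X[1:3, ] <- X[1:3, ] + rep(runif(2, 0.5, 2), each = 3)
    y <- rep(c("cancer", "control"), each = 3)
    fit <- fisher_fit(X, y)
    ang <- atan2(fit$coefficients[2], fit$coefficients[1]) %% pi
    diff <- abs(ang - fisher_angle_oracle(X, y) %% pi)
    expect_lt(min(diff, pi - diff), 1e-6)
  }
})

test_that("classifications agree with an independent LDA implementation", {
  skip_if_not_installed("MASS")
  set.seed(5)
  X <- matrix(rnorm(60), 20, 3)
  X[1:8, 1] <- X[1:8, 1] + 1.5
  y <- factor(rep(c("cancer", "control"), c(8, 12)),
              levels = c("cancer", "control"))
  fit <- fisher_fit(X, y)
  mine <- vapply(seq_len(nrow(X)), function(i) classify(fit, X[i, ])$label,
                 character(1))
  ref <- MASS::lda(X, grouping = y, prior = c(0.5, 0.5))
  expect_equal(mine, as.character(predict(ref, X)$class))
})

test_that("discriminant classifications are invariant under invertible affine feature maps", {
  set.seed(13)
  X <- matrix(rnorm(60), 20, 3)
  X[1:9, ] <- X[1:9, ] + 1
  y <- rep(c("cancer", "control"), c(9, 11))
  A <- matrix(c(2, 0.5, 0, -0.3, 1.5, 0.2, 0.1, 0, 1), 3, 3)
  b <- c(5, -2, 1)
  Xa <- X %*% A + matrix(b, 20, 3, byrow = TRUE)
  f1 <- fisher_fit(X, y)
  f2 <- fisher_fit(Xa, y)
  l1 <- vapply(seq_len(20), function(i) classify(f1, X[i, ])$label, character(1))
  l2 <- vapply(seq_len(20), function(i) classify(f2, Xa[i, ])$label, character(1))
  expect_equal(l1, l2)
})

test_that("stepwise selection finds the informative feature first, matching an exhaustive scan", {
  set.seed(9)
  n <- 30; p <- 60
  X <- matrix(rnorm(n * p), n, p)
  y <- rep(c("cancer", "control"), c(12, 18))
  X[y == "cancer", 17] <- X[y == "cancer", 17] + 3
  sel <- forward_stepwise_select(X, y, max_features = 3)
  lam <- wilks_scan(X, y)
  expect_equal(which.min(lam), 17)
  expect_equal(sel$indices[1], which.min(lam))
})

test_that("the tolerance guard keeps duplicated (collinear) features out", {
  set.seed(23)
  X <- matrix(rnorm(200), 20, 10)
  y <- rep(c("cancer", "control"), each = 10)
  X[y == "cancer", 2] <- X[y == "cancer", 2] + 2
  X[, 5] <- X[, 2]  # exact duplicate: tolerance 0 against column 2
  sel <- forward_stepwise_select(X, y, max_features = 6)
  expect_true(2 %in% sel$indices || 5 %in% sel$indices)
  expect_false(all(c(2, 5) %in% sel$indices))
  expect_true(all(sel$tolerance >= 0.001))
})

test_that("Wilks' lambda is non-increasing and selection size is capped", {
  coh <- simulate_cohort(small_sim_config(seed = 2))
  sel <- forward_stepwise_select(coh, max_features = 9)
  expect_lte(length(sel$indices), 9)
  expect_true(all(diff(c(1, sel$wilks)) <= 1e-10))
  expect_true(all(sel$f_enter > 3.84))
  ## cap must not exceed the smallest group size (10 here)
  expect_error(forward_stepwise_select(coh, max_features = 11),
               "smallest group size")
})

test_that("LOO cross-validation is perfect on a separable toy cohort and conserves counts", {
  coh <- toy_cohort()
  cv <- lda_loocv(coh, max_features = 2)
  expect_equal(cv$confusion$fn + cv$confusion$fp, 0)
  expect_equal(with(cv$confusion, tp + fn + fp + tn), 4)

  ## with one sample held out the smaller group has a single member, so the
  ## refit selection may enter at most one feature
  cvr <- lda_loocv(coh, protocol = "reselect_per_fold", max_features = 1)
  expect_equal(with(cvr$confusion, tp + fn + fp + tn), 4)

  coh2 <- simulate_cohort(small_sim_config(seed = 6))
  cv2 <- lda_loocv(coh2)
  expect_equal(with(cv2$confusion, tp + fn + fp + tn), nrow(coh2$X))
})

test_that("missing features in a short profile raise an error", {
  set.seed(3)
  X <- matrix(rnorm(40), 20, 2)
  y <- rep(c("cancer", "control"), each = 10)
  X[y == "cancer", ] <- X[y == "cancer", ] + 2
  fit <- fisher_fit(X, y, feature_indices = c(50, 90))
  expect_error(classify(fit, rnorm(10)), "too short")
})

test_that("resubstitution accuracy dominates LOO accuracy across replicates", {
  wins <- 0
  for (s in 1:20) {
    cv <- lda_loocv(simulate_cohort(small_sim_config(seed = s)))
    if (cv$within_confusion$accuracy >= cv$confusion$accuracy) wins <- wins + 1
  }
  expect_gte(wins, 18)  # >= 90% of 20 replicates
})
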