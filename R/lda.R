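## Method 1: two-group Fisher linear discriminant over time-point features,
## with forward stepwise selection under Wilks' lambda, an F-to-enter stopping
## rule, and a tolerance (multicollinearity) guard.

## Resolve (X, labels) from either a cohort or an explicit matrix.
resolve_xy <- function(x, labels) {
  if (is_cohort(x)) {
    list(X = cohort_matrix(x, standardize = TRUE), y = cohort_labels(x))
  } else {
    if (is.null(labels)) stop("labels are required when x is a matrix", call. = FALSE)
    y <- factor(labels)
    if ("cancer" %in% levels(y))
      y <- factor(y, levels = c("cancer", setdiff(levels(y), "cancer")))
    list(X = as.matrix(x), y = y)
  }
}

#' Forward stepwise time-point selection for two-group LDA
#'
#' Greedy forward selection over candidate time points: at each step the
#' candidate minimizing Wilks' lambda of the augmented model enters, provided
#' its tolerance (1 minus the within-group R-squared against the already
#' selected features) is at least `tolerance_floor` and its entry F-statistic
#' exceeds `entry_threshold`. Selection stops at `max_features`, which may not
#' exceed the smallest group size, so the model can never hold more predictors
#' than the smaller group has samples.
#'
#' The scan is incremental: with selected set S, the candidate's conditional
#' within-group and total sums of squares are Schur complements of the
#' within-group and total scatter matrices, so each step costs one `k x p`
#' cross-product rather than `p` determinant evaluations.
#'
#' @param x a `cohort` (profiles standardized internally) or a numeric
#'   `n x p` feature matrix of standardized values.
#' @param labels binary group labels when `x` is a matrix; ignored for a
#'   cohort.
#' @param max_features maximum number of time points to enter.
#' @param tolerance_floor minimum tolerance for entry (guards
#'   multicollinearity).
#' @param entry_threshold F-to-enter; selection stops when no candidate
#'   exceeds it.
#' @param prescreen optional count: restrict the stepwise scan to the
#'   `prescreen` candidates with smallest single-feature Wilks' lambda
#'   (`Inf` = scan all candidates, the default).
#' @return an object of class `selected_features`: list with `indices` (entry
#'   order), per-step `wilks` (cumulative Wilks' lambda, non-increasing),
#'   `f_enter` and `tolerance`.
#' @seealso [fisher_fit()], [lda_loocv()]
#' @export
forward_stepwise_select <- function(x, labels = NULL, max_features = 9L,
                                    tolerance_floor = 0.001,
                                    entry_threshold = 3.84,
                                    prescreen = Inf) {
  xy <- resolve_xy(x, labels)
  X <- xy$X; y <- xy$y
  if (nlevels(droplevels(y)) != 2)
    stop("cohort must contain exactly two non-empty groups", call. = FALSE)
  y <- droplevels(y)
  n <- nrow(X); p <- ncol(X)
  ng <- table(y)
  if (max_features > min(ng))
    stop("max_features may not exceed the smallest group size", call. = FALSE)
  if (tolerance_floor <= 0 || tolerance_floor >= 1)
    stop("tolerance_floor must lie in (0, 1)", call. = FALSE)

  gm <- rowsum(X, y) / as.vector(ng)          # 2 x p group means
  Xw <- X - gm[as.integer(y), , drop = FALSE] # within-group centered
  Xc <- sweep(X, 2, colMeans(X))              # grand centered
  Ediag <- colSums(Xw^2)
  Tdiag <- colSums(Xc^2)
  valid <- Ediag > 1e-10 & Tdiag > 1e-10

  if (is.finite(prescreen) && prescreen < p) {
    lam1 <- ifelse(valid, Ediag / Tdiag, Inf)
    keep <- order(lam1)[seq_len(prescreen)]
    valid <- valid & seq_len(p) %in% keep
  }

  S <- integer(0)
  wilks <- f_enter <- tolv <- numeric(0)
  Lambda <- 1
  repeat {
    k <- length(S)
    if (k >= max_features) break
    if (k == 0) {
      rw <- Ediag; rt <- Tdiag; tol <- rep(1, p)
    } else {
      Ess <- crossprod(Xw[, S, drop = FALSE])
      Tss <- crossprod(Xc[, S, drop = FALSE])
      CwS <- crossprod(Xw[, S, drop = FALSE], Xw)
      CcS <- crossprod(Xc[, S, drop = FALSE], Xc)
      rw <- pmax(Ediag - colSums(CwS * solve(Ess, CwS)), 0)
      rt <- pmax(Tdiag - colSums(CcS * solve(Tss, CcS)), 0)
      tol <- rw / Ediag
    }
    lam <- ifelse(valid & rt > 1e-12, pmin(pmax(rw / rt, 0), 1), Inf)
    lam[S] <- Inf
    lam[tol < tolerance_floor] <- Inf
    j <- which.min(lam)
    if (!is.finite(lam[j])) break
    Fj <- (n - 2 - k) * (1 - lam[j]) / max(lam[j], 1e-300)
    if (Fj < entry_threshold) break
    S <- c(S, j)
    Lambda <- Lambda * lam[j]
    wilks <- c(wilks, Lambda)
    f_enter <- c(f_enter, Fj)
    tolv <- c(tolv, tol[j])
  }
  structure(list(indices = S, wilks = wilks, f_enter = f_enter,
                 tolerance = tolv, n = n, group_sizes = as.vector(ng),
                 entry_threshold = entry_threshold,
                 tolerance_floor = tolerance_floor),
            class = "selected_features")
}

#' @export
print.selected_features <- function(x, ...) {
  cat(sprintf("Forward stepwise selection: %d time point(s) entered\n",
              length(x$indices)))
  if (length(x$indices)) {
    print(data.frame(step = seq_along(x$indices), t = x$indices,
                     wilks_lambda = signif(x$wilks, 4),
                     F_to_enter = signif(x$f_enter, 4),
                     tolerance = signif(x$tolerance, 4)),
          row.names = FALSE)
  }
  invisible(x)
}

#' Fit a two-group Fisher linear discriminant
#'
#' Classical two-group LDA on a set of selected features: the discriminant
#' direction is `pooled-within-covariance^{-1} %*% (mean difference)`, and the
#' decision threshold combines the projected group means with the prior odds.
#' A sample projects to the cancer side when its score exceeds the threshold;
#' exact ties are assigned to control.
#'
#' @param x numeric `n x k` matrix of standardized values on the selected
#'   features (or a `cohort`, in which case `feature_indices` selects
#'   columns).
#' @param labels binary group labels (levels `cancer`, `control`; the first
#'   level is the positive class for other label sets).
#' @param priors length-2 prior probabilities `(positive, negative)`; equal by
#'   default despite group-size imbalance (proportional priors can be passed
#'   explicitly).
#' @param feature_indices time-point indices the columns of `x` refer to;
#'   stored so full profiles can be classified.
#' @return an object of class `lda_model`: `coefficients`, `threshold`,
#'   `group_means`, `priors`, `levels`, `feature_indices`.
#' @seealso [classify()], [forward_stepwise_select()]
#' @export
fisher_fit <- function(x, labels = NULL, priors = c(0.5, 0.5),
                       feature_indices = NULL) {
  if (is_cohort(x)) {
    if (is.null(feature_indices))
      stop("feature_indices are required when fitting from a cohort", call. = FALSE)
    X <- cohort_matrix(x, standardize = TRUE)[, feature_indices, drop = FALSE]
    y <- cohort_labels(x)
  } else {
    xy <- resolve_xy(x, labels)
    X <- xy$X; y <- xy$y
  }
  y <- droplevels(y)
  if (nlevels(y) != 2) stop("both groups must be non-empty", call. = FALSE)
  if (length(priors) != 2 || any(priors <= 0))
    stop("priors must be two positive probabilities", call. = FALSE)
  priors <- priors / sum(priors)

  pos <- levels(y)[1]; neg <- levels(y)[2]
  m_pos <- colMeans(X[y == pos, , drop = FALSE])
  m_neg <- colMeans(X[y == neg, , drop = FALSE])
  n_pos <- sum(y == pos); n_neg <- sum(y == neg)
  Xp <- sweep(X[y == pos, , drop = FALSE], 2, m_pos)
  Xn <- sweep(X[y == neg, , drop = FALSE], 2, m_neg)
  Sp <- (crossprod(Xp) + crossprod(Xn)) / (n_pos + n_neg - 2)
  R <- tryCatch(chol(Sp), error = function(e) NULL)
  if (is.null(R))
    stop("pooled within-group covariance is singular on the selected features (multicollinearity)",
         call. = FALSE)
  w <- backsolve(R, backsolve(R, m_pos - m_neg, transpose = TRUE))
  threshold <- 0.5 * sum(w * (m_pos + m_neg)) + log(priors[2] / priors[1])
  structure(list(coefficients = as.vector(w), threshold = threshold,
                 group_means = rbind(pos = m_pos, neg = m_neg),
                 priors = priors, levels = c(pos, neg),
                 feature_indices = feature_indices %||% seq_len(ncol(X))),
            class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("Two-group linear discriminant: %d feature(s), priors %.2f/%.2f\n",
              length(x$coefficients), x$priors[1], x$priors[2]))
  cat("  t indices:   ", paste(x$feature_indices, collapse = ", "), "\n")
  cat("  coefficients:", paste(signif(x$coefficients, 4), collapse = ", "), "\n")
  cat(sprintf("  threshold: %.4f  (positive class: %s)\n", x$threshold, x$levels[1]))
  invisible(x)
}

#' Classify a standardized profile with a fitted discriminant
#'
#' Projects the profile's selected features onto the discriminant direction
#' and compares against the threshold. The signed distance from the threshold
#' is returned as the score; a tie exactly at the threshold is assigned to the
#' negative (control) class.
#'
#' @param model an `lda_model`.
#' @param profile numeric vector: either a full standardized profile (indexed
#'   by the model's `feature_indices`) or a vector of exactly the selected
#'   features.
#' @return list with `label` and `score`.
#' @export
classify <- function(model, profile) {
  stopifnot(inherits(model, "lda_model"))
  k <- length(model$coefficients)
  if (length(profile) == k) {
    v <- profile
  } else {
    if (max(model$feature_indices) > length(profile))
      stop("profile is too short for the model's feature indices", call. = FALSE)
    v <- profile[model$feature_indices]
  }
  score <- sum(model$coefficients * v) - model$threshold
  list(label = if (score > 0) model$levels[1] else model$levels[2],
       score = score)
}

classify_matrix <- function(model, X) {
  scores <- as.vector(X[, model$feature_indices, drop = FALSE] %*%
                        model$coefficients) - model$threshold
  list(label = ifelse(scores > 0, model$levels[1], model$levels[2]),
       score = scores)
}

#' Leave-one-out cross-validation of the stepwise discriminant
#'
#' For each sample: hold it out, fit on the remainder, predict it. Two
#' protocols are offered. `"fixed_features"` (the default) selects the time
#' points once on the full sample and refits only the discriminant
#' coefficients in each fold, mirroring classical stepwise-DA software;
#' `"reselect_per_fold"` repeats the entire stepwise selection inside every
#' fold, which is the fully honest protocol (and the one that stays at chance
#' on null data).
#'
#' @param cohort a `cohort` object (>= 2 samples per group).
#' @param protocol `"fixed_features"` or `"reselect_per_fold"`.
#' @param max_features,tolerance_floor,entry_threshold,prescreen selection
#'   parameters, see [forward_stepwise_select()].
#' @param priors passed to [fisher_fit()].
#' @return an object of class `lda_loocv`: list with `confusion` (a
#'   [confusion()] matrix of LOO predictions), `predictions`, `features` (the
#'   full-sample selection), and `within_confusion` (resubstitution
#'   predictions of the full-sample model).
#' @export
lda_loocv <- function(cohort, protocol = c("fixed_features", "reselect_per_fold"),
                      max_features = 9L, tolerance_floor = 0.001,
                      entry_threshold = 3.84, priors = c(0.5, 0.5),
                      prescreen = Inf) {
  stopifnot(is_cohort(cohort))
  protocol <- match.arg(protocol)
  y <- droplevels(cohort_labels(cohort))
  if (nlevels(y) != 2 || any(table(y) < 2))
    stop("LOO-CV needs at least 2 samples per group", call. = FALSE)
  Z <- cohort_matrix(cohort, standardize = TRUE)
  n <- nrow(Z)

  sel <- forward_stepwise_select(Z, y, max_features = max_features,
                                 tolerance_floor = tolerance_floor,
                                 entry_threshold = entry_threshold,
                                 prescreen = prescreen)
  full_fit <- fisher_fit(Z[, sel$indices, drop = FALSE], y, priors = priors,
                         feature_indices = sel$indices)
  within_pred <- classify_matrix(full_fit, Z)$label

  pred <- character(n)
  score <- numeric(n)
  for (i in seq_len(n)) {
    yi <- droplevels(y[-i])
    if (nlevels(yi) != 2)
      stop("LOO fold with an empty group", call. = FALSE)
    idx <- if (protocol == "fixed_features") {
      sel$indices
    } else {
      forward_stepwise_select(Z[-i, , drop = FALSE], yi,
                              max_features = max_features,
                              tolerance_floor = tolerance_floor,
                              entry_threshold = entry_threshold,
                              prescreen = prescreen)$indices
    }
    if (length(idx) == 0) {
      ## empty model: fall back to the prior-majority class
      pred[i] <- full_fit$levels[which.max(priors)]
      score[i] <- 0
      next
    }
    fit <- fisher_fit(Z[-i, idx, drop = FALSE], yi, priors = priors,
                      feature_indices = idx)
    cl <- classify(fit, Z[i, idx])
    pred[i] <- cl$label
    score[i] <- cl$score
  }
  structure(list(
    confusion = confusion(y, pred),
    within_confusion = confusion(y, within_pred),
    predictions = data.frame(sample_id = cohort$meta$sample_id,
                             group = as.character(y), predicted = pred,
                             score = score, stringsAsFactors = FALSE),
    features = sel, protocol = protocol
  ), class = "lda_loocv")
}

#' @export
print.lda_loocv <- function(x, ...) {
  cat(sprintf("Stepwise-LDA leave-one-out cross-validation (%s protocol)\n",
              x$protocol))
  cat("Selected time points:", paste(x$features$indices, collapse = ", "), "\n")
  cat("\nOriginal model (within sample):\n")
  print(x$within_confusion)
  cat("\nCross-validation (leave-one-out):\n")
  print(x$confusion)
  invisible(x)
}
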