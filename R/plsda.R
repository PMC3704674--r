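## Method 2: two-group PLS-DA over the entire standardized profile.
## PLS1 (univariate response) via NIPALS: for a binary indicator response each
## factor extraction is a single closed-form pass, so the fit is exact and
## deterministic. Class coding is control = 0, cancer = 1 with decision
## threshold 0.5; predictors are deflated, the response is not (redundant for
## a univariate y). Columns are centered inside the fit; no per-column scaling
## is applied on top of the within-profile standardization.

#' Fit a two-group PLS-DA model
#'
#' Extracts `n_factors` latent factors from the (column-centered) predictor
#' matrix against the centered binary class indicator. Each factor's weight
#' vector is the unit-norm direction maximizing covariance between the
#' deflated predictors' scores and the centered indicator; the predictors are
#' then deflated by the rank-one score-loading product. The regression
#' coefficients composing all factors map a centered profile to a response
#' score.
#'
#' @param x a `cohort` (profiles standardized internally) or a numeric
#'   `n x p` matrix.
#' @param labels binary group labels when `x` is a matrix (`cancer` is coded
#'   1, `control` 0; for other label sets the first factor level is coded 1).
#' @param n_factors number of latent factors, `1 <= n_factors <= n - 1` (the
#'   factor sweep uses up to ten).
#' @param decision_threshold score cut for classification (default 0.5, the
#'   midpoint of the 0/1 coding).
#' @return an object of class `plsda_model`: `x_weights`, `x_loadings`
#'   (`p x A`), `y_loadings` (length `A`), `scores` (`n x A`, mutually
#'   orthogonal), `coefficients` (length `p`), `x_mean`, `y_mean`,
#'   `class_coding`, `decision_threshold`.
#' @seealso [plsda_predict()], [plsda_loocv_sweep()]
#' @export
plsda_fit <- function(x, labels = NULL, n_factors, decision_threshold = 0.5) {
  xy <- resolve_xy(x, labels)
  X <- xy$X; y <- droplevels(xy$y)
  if (nlevels(y) != 2) stop("both groups must be present", call. = FALSE)
  n <- nrow(X)
  if (!is.numeric(n_factors) || length(n_factors) != 1L || n_factors < 1)
    stop("n_factors must be >= 1", call. = FALSE)
  if (n_factors > n - 1)
    stop("n_factors exceeds the feasible rank (n - 1)", call. = FALSE)
  n_factors <- as.integer(n_factors)
  pos <- levels(y)[1]; neg <- levels(y)[2]
  yv <- as.numeric(y == pos)

  x_mean <- colMeans(X)
  E <- sweep(X, 2, x_mean)
  y_mean <- mean(yv)
  f <- yv - y_mean
  p <- ncol(X)
  W <- P <- matrix(0, p, n_factors)
  Tm <- matrix(0, n, n_factors)
  q <- numeric(n_factors)
  for (a in seq_len(n_factors)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12)
      stop(sprintf("predictor rank exhausted at factor %d", a), call. = FALSE)
    w <- w / nw
    t_ <- as.vector(E %*% w)
    tt <- sum(t_^2)
    if (tt < 1e-12)
      stop(sprintf("predictor rank exhausted at factor %d", a), call. = FALSE)
    pv <- crossprod(E, t_) / tt
    q[a] <- sum(f * t_) / tt
    E <- E - tcrossprod(t_, pv)
    W[, a] <- w; P[, a] <- pv; Tm[, a] <- t_
  }
  B <- plsda_coefficients(W, P, q, n_factors)
  structure(list(n_factors = n_factors, x_weights = W, x_loadings = P,
                 y_loadings = q, scores = Tm, coefficients = B,
                 x_mean = x_mean, y_mean = y_mean,
                 class_coding = c(pos = 1, neg = 0), levels = c(pos, neg),
                 decision_threshold = decision_threshold),
            class = "plsda_model")
}

## Regression coefficients using the first `a` factors: B_a = W_a (P_a' W_a)^{-1} q_a.
plsda_coefficients <- function(W, P, q, a) {
  Wa <- W[, seq_len(a), drop = FALSE]
  Pa <- P[, seq_len(a), drop = FALSE]
  as.vector(Wa %*% solve(crossprod(Pa, Wa), q[seq_len(a)]))
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf("PLS-DA model: %d latent factor(s) over %d predictors\n",
              x$n_factors, length(x$coefficients)))
  cat(sprintf("  class coding: %s = 1, %s = 0; decision threshold %.2f\n",
              x$levels[1], x$levels[2], x$decision_threshold))
  cat(sprintf("  y loadings: %s\n", paste(signif(x$y_loadings, 4), collapse = ", ")))
  invisible(x)
}

#' Predict class membership with a fitted PLS-DA model
#'
#' Response score `y_mean + coefficients . (profile - x_mean)`; the sample is
#' called cancer when the score exceeds the decision threshold, with an exact
#' tie assigned to control.
#'
#' @param model a `plsda_model`.
#' @param profile numeric profile on the model's grid, or an `n x p` matrix of
#'   profiles.
#' @param n_factors optionally predict with only the first `n_factors` of the
#'   stored factors.
#' @return for a single profile, list with `label` and `score`; for a matrix,
#'   list of vectors `label` and `score`.
#' @export
plsda_predict <- function(model, profile, n_factors = NULL) {
  stopifnot(inherits(model, "plsda_model"))
  B <- if (is.null(n_factors)) {
    model$coefficients
  } else {
    if (n_factors < 1 || n_factors > model$n_factors)
      stop("n_factors outside the stored factor range", call. = FALSE)
    plsda_coefficients(model$x_weights, model$x_loadings, model$y_loadings,
                       n_factors)
  }
  one <- is.null(dim(profile))
  Xn <- if (one) matrix(profile, 1) else as.matrix(profile)
  if (ncol(Xn) != length(model$x_mean))
    stop("profile grid does not match the model", call. = FALSE)
  score <- as.vector(sweep(Xn, 2, model$x_mean) %*% B) + model$y_mean
  label <- ifelse(score > model$decision_threshold,
                  model$levels[1], model$levels[2])
  if (one) list(label = label[1], score = score[1])
  else list(label = label, score = score)
}

#' Latent-factor sweep with leave-one-out classification
#'
#' For each factor count `1..max_factors`, fits the PLS-DA classifier on the
#' full cohort for within-sample (resubstitution) counts and refits it on
#' every leave-one-out subset (centering included) to predict the held-out
#' sample, reporting per-group correct counts and percentages in the layout of
#' the published factor-sweep table.
#'
#' @param cohort a `cohort` object (>= 3 samples per group).
#' @param max_factors maximum latent factors (default 10).
#' @return a data.frame of class `plsda_sweep` with one row per factor count:
#'   `n_factors`, within-sample and LOO correct counts and percentages for the
#'   cancer and control groups.
#' @export
plsda_loocv_sweep <- function(cohort, max_factors = 10L) {
  stopifnot(is_cohort(cohort))
  if (!is.numeric(max_factors) || max_factors < 1)
    stop("max_factors must be >= 1", call. = FALSE)
  max_factors <- as.integer(max_factors)
  y <- droplevels(cohort_labels(cohort))
  if (nlevels(y) != 2 || any(table(y) < 3))
    stop("factor sweep needs at least 3 samples per group", call. = FALSE)
  Z <- cohort_matrix(cohort, standardize = TRUE)
  n <- nrow(Z)
  if (max_factors > n - 2)
    stop("max_factors exceeds the feasible rank for LOO refits", call. = FALSE)
  pos <- levels(y)[1]; neg <- levels(y)[2]

  full <- plsda_fit(Z, y, n_factors = max_factors)
  within <- vapply(seq_len(max_factors), function(a) {
    plsda_predict(full, Z, n_factors = a)$label
  }, character(n))

  loo <- matrix(NA_character_, n, max_factors)
  for (i in seq_len(n)) {
    fit_i <- plsda_fit(Z[-i, , drop = FALSE], y[-i], n_factors = max_factors)
    for (a in seq_len(max_factors)) {
      loo[i, a] <- plsda_predict(fit_i, Z[i, ], n_factors = a)$label
    }
  }

  n_pos <- sum(y == pos); n_neg <- sum(y == neg)
  count <- function(pred, grp) sum(pred[y == grp] == grp)
  rows <- lapply(seq_len(max_factors), function(a) {
    wc_pos <- count(within[, a], pos); wc_neg <- count(within[, a], neg)
    lc_pos <- count(loo[, a], pos);    lc_neg <- count(loo[, a], neg)
    data.frame(n_factors = a,
               within_cancer = wc_pos, within_cancer_pct = 100 * wc_pos / n_pos,
               within_control = wc_neg, within_control_pct = 100 * wc_neg / n_neg,
               loo_cancer = lc_pos, loo_cancer_pct = 100 * lc_pos / n_pos,
               loo_control = lc_neg, loo_control_pct = 100 * lc_neg / n_neg)
  })
  out <- do.call(rbind, rows)
  attr(out, "group_sizes") <- c(cancer = n_pos, control = n_neg)
  class(out) <- c("plsda_sweep", "data.frame")
  out
}

#' @export
print.plsda_sweep <- function(x, ...) {
  gs <- attr(x, "group_sizes")
  cat("PLS-DA factor sweep: correct classifications by latent-factor count\n")
  cat(sprintf("  (%d cancer, %d control)\n\n", gs[1], gs[2]))
  fmt <- function(cnt, pct) sprintf("%d (%s)", cnt, formatC(pct, format = "f", digits = 1))
  disp <- data.frame(
    factors = x$n_factors,
    within_bladder = fmt(x$within_cancer, x$within_cancer_pct),
    within_control = fmt(x$within_control, x$within_control_pct),
    loo_bladder = fmt(x$loo_cancer, x$loo_cancer_pct),
    loo_control = fmt(x$loo_control, x$loo_control_pct))
  print(disp, row.names = FALSE)
  invisible(x)
}
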