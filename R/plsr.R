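#' Fit a univariate PLSR model by SIMPLS
#'
#' Deterministic SIMPLS deflation (de Jong's algorithm) for a single
#' response. Predictors and response are mean-centered internally (no
#' variance scaling, the usual convention for absorbance spectra); the
#' centering is stored so that `predict()` works on raw inputs. Regression
#' coefficient vectors are available for every component count up to
#' `n_components`.
#'
#' @param X Numeric matrix, samples x bands.
#' @param y Numeric response vector (SOM % w/w).
#' @param n_components Number of latent variables f, `1 <= f <=
#'   min(nrow(X) - 1, ncol(X))`.
#' @param wavelengths Optional band wavelengths stored with the model.
#' @return An object of class `simpls_model` with elements `coefficients`
#'   (bands x n_components matrix; column k is the coefficient vector of the
#'   k-component model), `intercepts`, `x_center`, `y_center`,
#'   `n_components`, `scores`, `x_loadings`, `y_loadings`, `wavelengths`.
#' @export
simpls_fit <- function(X, y, n_components, wavelengths = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  kmax <- min(n - 1L, p)
  if (n_components < 1L || n_components > kmax) {
    stop("n_components must be between 1 and min(samples - 1, bands) = ", kmax)
  }
  x_center <- colMeans(X)
  y_center <- mean(y)
  X0 <- sweep(X, 2, x_center)
  y0 <- y - y_center

  R <- matrix(0, p, n_components)   # weight vectors (raw-X basis)
  P <- matrix(0, p, n_components)   # X loadings
  Tm <- matrix(0, n, n_components)  # scores
  q <- numeric(n_components)        # y loadings
  V <- matrix(0, p, n_components)   # orthonormal basis of loadings
  s <- crossprod(X0, y0)
  a <- 0L
  for (k in seq_len(n_components)) {
    r <- s
    t <- X0 %*% r
    nt <- sqrt(sum(t^2))
    if (nt < 1e-12 * max(1, sqrt(sum(X0^2)))) {
      warning("rank deficiency: components capped at ", a)
      break
    }
    t <- t / nt; r <- r / nt
    pk <- crossprod(X0, t)
    qk <- sum(y0 * t)
    v <- pk
    if (k > 1L) {
      Vk <- V[, seq_len(k - 1L), drop = FALSE]
      v <- v - Vk %*% crossprod(Vk, v)
    }
    v <- v / sqrt(sum(v^2))
    s <- s - v %*% crossprod(v, s)
    R[, k] <- r; P[, k] <- pk; Tm[, k] <- t; q[k] <- qk; V[, k] <- v
    a <- k
  }
  if (a == 0L) stop("X has rank 0 after centering")
  R <- R[, seq_len(a), drop = FALSE]
  P <- P[, seq_len(a), drop = FALSE]
  Tm <- Tm[, seq_len(a), drop = FALSE]
  q <- q[seq_len(a)]
  coefs <- sapply(seq_len(a), function(k) {
    R[, seq_len(k), drop = FALSE] %*% q[seq_len(k)]
  })
  coefs <- matrix(coefs, nrow = p)
  intercepts <- y_center - as.numeric(crossprod(x_center, coefs))
  structure(list(coefficients = coefs, intercepts = intercepts,
                 x_center = x_center, y_center = y_center,
                 n_components = a, scores = Tm, x_loadings = P,
                 y_loadings = q, wavelengths = wavelengths),
            class = "simpls_model")
}

#' Predict from a SIMPLS model
#'
#' @param object A `simpls_model`.
#' @param newdata Numeric matrix, samples x bands (same bands as the fit).
#' @param ncomp Component count(s) to use; defaults to the full fit. With
#'   several values a matrix with one column per count is returned.
#' @param ... Unused.
#' @return Numeric vector (or matrix) of predictions.
#' @export
predict.simpls_model <- function(object, newdata, ncomp = object$n_components, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != nrow(object$coefficients)) {
    stop("newdata has ", ncol(newdata), " bands; model expects ",
         nrow(object$coefficients))
  }
  if (any(ncomp < 1L | ncomp > object$n_components)) {
    stop("ncomp out of fitted range")
  }
  out <- newdata %*% object$coefficients[, ncomp, drop = FALSE]
  out <- sweep(out, 2, object$intercepts[ncomp], "+")
  if (length(ncomp) == 1L) as.numeric(out) else out
}

#' @export
print.simpls_model <- function(x, ...) {
  cat("<simpls_model> ", nrow(x$coefficients), " band(s), ",
      x$n_components, " component(s)\n", sep = "")
  invisible(x)
}

# Pooled cross-validated RMSE per component count. Returns a list with
# rmsecv (vector over 1..kmax), predictions (n x kmax matrix of out-of-fold
# predictions) and the fold assignment.
cv_components <- function(X, y, folds = 5, max_components = 15, seed = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (folds < 2L || folds > n) stop("folds must be in [2, n]")
  set.seed(seed)
  fold_id <- sample(rep(seq_len(folds), length.out = n))
  kmax <- min(max_components, ncol(X),
              n - max(tabulate(fold_id, folds)) - 1L)
  kmax <- max(kmax, 1L)
  pred <- matrix(NA_real_, n, kmax)
  for (f in seq_len(folds)) {
    test <- fold_id == f
    fit <- simpls_fit(X[!test, , drop = FALSE], y[!test],
                      min(kmax, sum(!test) - 1L, ncol(X)))
    k_avail <- seq_len(min(kmax, fit$n_components))
    pred[test, k_avail] <- predict(fit, X[test, , drop = FALSE], ncomp = k_avail)
  }
  rmsecv <- apply(pred, 2, function(yp) sqrt(mean((yp - y)^2)))
  list(rmsecv = rmsecv, predictions = pred, fold_id = fold_id)
}

#' Choose the PLSR component count by cross-validation
#'
#' Returns the latent-variable count f minimising the pooled cross-validated
#' RMSE over `1..max_components`; ties go to the smallest f. Deterministic
#' given the seed (which drives the fold shuffle).
#'
#' @param X Predictor matrix, samples x bands.
#' @param y Response vector.
#' @param folds Number of CV folds.
#' @param max_components Largest f considered (capped by data size).
#' @param seed Integer seed for the fold assignment.
#' @return The chosen integer f.
#' @export
choose_components <- function(X, y, folds = 5, max_components = 15, seed = 1L) {
  cv <- cv_components(X, y, folds, max_components, seed)
  which.min(cv$rmsecv)  # first minimum = smallest f on ties
}

#' Coefficient of determination
#'
#' `R2 = 1 - sum((y_pred - y_true)^2) / sum((y_true - mean(y_true))^2)`.
#'
#' @param y_true Measured values (at least 2, non-constant).
#' @param y_pred Predicted values, same length.
#' @return R-squared (can be negative for predictions worse than the mean).
#' @export
r_squared <- function(y_true, y_pred) {
  if (length(y_true) < 2L || length(y_true) != length(y_pred)) {
    stop("need >= 2 paired observations")
  }
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) stop("zero variance in y_true")
  1 - sum((y_pred - y_true)^2) / ss_tot
}

#' Root-mean-square error for a prediction role
#'
#' The three RMSE variants differ only in the denominator:
#' calibration uses `Ic - f - 1` degrees of freedom (f = component count),
#' cross-validation uses `Icv`, prediction uses `Ip`.
#'
#' @param y_true,y_pred Paired measured and predicted values.
#' @param role One of `"calibration"`, `"validation"`, `"prediction"`.
#' @param f Component count; required for `role = "calibration"`.
#' @return Non-negative scalar in the units of `y`.
#' @export
rmse_metric <- function(y_true, y_pred,
                        role = c("calibration", "validation", "prediction"),
                        f = NULL) {
  role <- match.arg(role)
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  ss <- sum((y_pred - y_true)^2)
  n <- length(y_true)
  if (role == "calibration") {
    if (is.null(f)) stop("f is required for calibration RMSE")
    if (n - f - 1 <= 0) stop("degrees of freedom Ic - f - 1 must be positive")
    sqrt(ss / (n - f - 1))
  } else {
    sqrt(ss / n)
  }
}

#' Ratio of performance to deviation
#'
#' `RPD = SD / RMSEP`, where SD is the standard deviation of the reference
#' (calibration-set) measured values.
#'
#' @param sd_reference Standard deviation of the calibration-set response.
#' @param rmsep Root-mean-square error of prediction, `> 0`.
#' @return The RPD ratio; `Inf` (with a warning) when `rmsep` is 0.
#' @export
rpd <- function(sd_reference, rmsep) {
  if (rmsep < 0) stop("rmsep must be non-negative")
  if (rmsep == 0) {
    warning("rmsep is 0; RPD is infinite")
    return(Inf)
  }
  sd_reference / rmsep
}

#' Qualitative RPD class
#'
#' Standard chemometric interpretation bands: RPD < 1.4 unacceptable;
#' 1.4-1.8 fair; 1.8-2.0 good; 2.0-2.5 very good; >= 2.5 excellent
#' (intervals half-open on the right).
#'
#' @param x RPD value, `>= 0`.
#' @return One of `"unacceptable"`, `"fair"`, `"good"`, `"very_good"`,
#'   `"excellent"`.
#' @export
classify_rpd <- function(x) {
  if (x < 0) stop("rpd must be non-negative")
  if (x < 1.4) "unacceptable"
  else if (x < 1.8) "fair"
  else if (x < 2.0) "good"
  else if (x < 2.5) "very_good"
  else "excellent"
}

#' Run one band-selection PLSR experiment
#'
#' Nested five-fold evaluation of SOM prediction from a restricted band set:
#' samples are shuffled (seeded) into `folds` outer folds; each outer fold in
#' turn is the prediction set while the remainder is the calibration set. The
#' component count f is chosen per outer fold by inner cross-validation on
#' the calibration portion, which also yields RMSECV/R2cv (pooled inner
#' out-of-fold predictions, averaged across outer folds). R2c/RMSEC come from
#' the per-fold final fits (averaged); R2p/RMSEP from the pooled outer
#' out-of-fold predictions. RPD = mean calibration-set SD / pooled RMSEP.
#'
#' @param study A [spectrum_set] with `som_pct` for every sample.
#' @param bands A [band_set] restricting the predictors.
#' @param folds Number of outer folds (the inner loop uses the same number).
#' @param seed Integer seed controlling the fold shuffles.
#' @param max_components Largest latent-variable count considered.
#' @return An object of class `model_metrics`: list with `label`, `n_bands`,
#'   `r2_c`, `rmsec`, `r2_cv`, `rmsecv`, `r2_p`, `rmsep`, `rpd`, `rpd_class`,
#'   `sd_reference`, `n_components` (median over folds), `f_per_fold`,
#'   `n_cal`, `n_pred`, `predictions` (data frame of pooled out-of-fold
#'   predictions).
#' @export
run_experiment <- function(study, bands, folds = 5, seed = 1L,
                           max_components = 15) {
  if (is.null(study$som_pct) || any(!is.finite(study$som_pct))) {
    stop("study lacks som_pct metadata for every sample")
  }
  sub <- apply_bandset(study, bands)
  X <- sub$absorbance
  y <- sub$som_pct
  n <- nrow(X)
  if (n < folds) stop("fewer samples than folds")
  set.seed(seed)
  fold_id <- sample(rep(seq_len(folds), length.out = n))
  y_pred <- rep(NA_real_, n)
  r2c <- rmsec <- r2cv <- rmsecv <- sdcal <- numeric(folds)
  f_used <- integer(folds)
  for (k in seq_len(folds)) {
    hold <- fold_id == k
    Xc <- X[!hold, , drop = FALSE]; yc <- y[!hold]
    inner <- cv_components(Xc, yc, folds = min(folds, length(yc)),
                           max_components = max_components, seed = seed + k)
    f_k <- which.min(inner$rmsecv)
    fit <- simpls_fit(Xc, yc, f_k)
    yc_hat <- predict(fit, Xc)
    yin_hat <- inner$predictions[, f_k]
    f_used[k] <- f_k
    r2c[k] <- r_squared(yc, yc_hat)
    rmsec[k] <- rmse_metric(yc, yc_hat, "calibration", f = f_k)
    r2cv[k] <- r_squared(yc, yin_hat)
    rmsecv[k] <- inner$rmsecv[f_k]
    sdcal[k] <- stats::sd(yc)
    y_pred[hold] <- predict(fit, X[hold, , drop = FALSE])
  }
  rmsep <- rmse_metric(y, y_pred, "prediction")
  rpd_val <- rpd(mean(sdcal), rmsep)
  structure(list(
    label = attr(bands, "label"),
    n_bands = ncol(X),
    r2_c = mean(r2c), rmsec = mean(rmsec),
    r2_cv = mean(r2cv), rmsecv = mean(rmsecv),
    r2_p = r_squared(y, y_pred), rmsep = rmsep,
    rpd = rpd_val, rpd_class = classify_rpd(rpd_val),
    sd_reference = mean(sdcal),
    n_components = as.integer(stats::median(f_used)),
    f_per_fold = f_used,
    n_cal = n - min(tabulate(fold_id, folds)), n_pred = n,
    predictions = data.frame(sample_id = sub$sample_ids, fold = fold_id,
                             y_true = y, y_pred = y_pred)
  ), class = "model_metrics")
}

#' @export
print.model_metrics <- function(x, ...) {
  cat("<model_metrics>", if (!is.null(x$label)) paste0(" [", x$label, "]"),
      " bands=", x$n_bands,
      sprintf(" R2c=%.3f RMSEC=%.3f R2cv=%.3f RMSECV=%.3f R2p=%.3f RMSEP=%.3f RPD=%.2f (%s)",
              x$r2_c, x$rmsec, x$r2_cv, x$rmsecv, x$r2_p, x$rmsep, x$rpd,
              x$rpd_class), "\n", sep = "")
  invisible(x)
}

#' One-row data frame of experiment metrics
#'
#' @param x A `model_metrics` object.
#' @param row.names,optional,... Standard [as.data.frame()] arguments, unused.
#' @return A single-row data frame in reporting column order.
#' @export
as.data.frame.model_metrics <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(label = if (is.null(x$label)) NA_character_ else x$label,
             n_bands = x$n_bands, n_components = x$n_components,
             r2_c = x$r2_c, rmsec = x$rmsec, r2_cv = x$r2_cv,
             rmsecv = x$rmsecv, r2_p = x$r2_p, rmsep = x$rmsep,
             rpd = x$rpd, rpd_class = x$rpd_class)
}
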