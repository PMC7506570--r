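# Independent oracles and small fixture builders shared across test files.

# Explicit double-loop sample covariance between all band pairs: the
# brute-force counterpart of the matrix-product synchronous map.
cov_oracle <- function(dyn) {
  m <- nrow(dyn); p <- ncol(dyn)
  out <- matrix(0, p, p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      out[i, j] <- sum(dyn[, i] * dyn[, j]) / (m - 1)
    }
  }
  out
}

# Minimal NIPALS PLS1: an implementation-independent reference for SIMPLS.
# Deflates X only (standard PLS1); returns fitted training predictions.
nipals_pls1 <- function(X, y, ncomp) {
  X0 <- scale(X, center = TRUE, scale = FALSE)
  y0 <- y - mean(y)
  Xd <- X0
  W <- P <- matrix(0, ncol(X), ncomp)
  Tm <- matrix(0, nrow(X), ncomp)
  q <- numeric(ncomp)
  for (k in seq_len(ncomp)) {
    w <- crossprod(Xd, y0)
    w <- w / sqrt(sum(w^2))
    t <- Xd %*% w
    p <- crossprod(Xd, t) / sum(t^2)
    q[k] <- sum(y0 * t) / sum(t^2)
    Xd <- Xd - t %*% t(p)
    W[, k] <- w; P[, k] <- p; Tm[, k] <- t
  }
  B <- W %*% solve(crossprod(P, W), q)
  as.numeric(X0 %*% B) + mean(y)
}

# Small deterministic spectrum_set with both metadata columns.
toy_study <- function(n_bands = 12, som = c(1, 2, 3, 4), moisture = c(0, 5, 10, 15)) {
  grid <- seq(500, 500 + n_bands - 1)
  design <- expand.grid(som = som, moisture = moisture)
  a <- outer(design$som, sin(grid / 50)) + outer(design$moisture, cos(grid / 80)) / 10
  spectrum_set(grid, a + 0.5,
               sample_ids = sprintf("t%02d", seq_len(nrow(design))),
               som_pct = design$som, moisture_pct = design$moisture)
}

# Default configuration with the quench interactions switched off: the
# planted SOM -> spectrum map is then linear, as assumed by the parameter
# recovery property.
linear_map_config <- function(...) {
  cfg <- default_synthetic_config(...)
  for (nm in names(cfg$peaks)) {
    cfg$peaks[[nm]]$quench_moisture <- NA_real_
    cfg$peaks[[nm]]$quench_som <- NA_real_
  }
  cfg
}

# Reduced grid for fast synthetic runs where full 2051-band maps are not the
# point.
small_cfg <- function(seed = 1L, ...) {
  default_synthetic_config(seed = seed, grid = seq(400, 2450, by = 5), ...)
}
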