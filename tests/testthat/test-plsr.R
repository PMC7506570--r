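test_that("SIMPLS reproduces exact, OLS and NIPALS references", {
  set.seed(21)
  # y exactly linear in one predictor, 1 component
  X <- cbind(runif(20), matrix(rnorm(20 * 4) * 1e-8, 20, 4))
  y <- 3 + 2 * X[, 1]
  f1 <- simpls_fit(X, y, 1)
  expect_equal(predict(f1, X), y, tolerance = 1e-8)

  # full component count equals the OLS solution (normal equations oracle)
  X <- matrix(rnorm(100), 20, 5)
  y <- rnorm(20)
  f <- simpls_fit(X, y, 5)
  Xc <- cbind(1, X)
  beta <- solve(crossprod(Xc), crossprod(Xc, y))
  expect_equal(unname(f$coefficients[, 5]), unname(beta[-1]), tolerance = 1e-8)
  expect_equal(predict(f, X, ncomp = 5), as.numeric(Xc %*% beta),
               tolerance = 1e-8)

  # NIPALS PLS1 oracle at intermediate component counts, several shapes
  for (dims in list(c(12, 6, 2), c(15, 30, 3), c(10, 4, 4))) {
    n <- dims[1]; p <- dims[2]; k <- dims[3]
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    expect_equal(predict(simpls_fit(X, y, k), X, ncomp = k),
                 nipals_pls1(X, y, k), tolerance = 1e-6)
  }

  # replicating all rows leaves the model unchanged
  f2 <- simpls_fit(rbind(X, X), c(y, y), 3)
  f3 <- simpls_fit(X, y, 3)
  expect_equal(f2$coefficients, f3$coefficients, tolerance = 1e-10)

  # rank deficiency caps the component count with a warning
  Xr <- cbind(1:8, 2 * (1:8), rnorm(8))
  expect_warning(fr <- simpls_fit(Xr, rnorm(8), 3), "rank deficiency")
  expect_lt(fr$n_components, 3)
  expect_error(simpls_fit(X, y, 0), "n_components")
  expect_error(simpls_fit(X, y, 50), "n_components")
})

test_that("component choice minimises pooled cross-validated error", {
  set.seed(4)
  # noiseless single-factor data -> 1 component suffices and is chosen
  t <- rnorm(30)
  X <- outer(t, seq(-1, 1, length.out = 10))
  y <- 2 * t + 5
  expect_equal(suppressWarnings(
    choose_components(X, y, folds = 5, max_components = 5, seed = 1)), 1L)
  # pure-noise response: RMSECV near sd(y), small f by the tie/first-min rule
  Xn <- matrix(rnorm(60 * 8), 60, 8)
  yn <- rnorm(60)
  cv <- soilcos:::cv_components(Xn, yn, folds = 5, max_components = 6, seed = 2)
  expect_equal(min(cv$rmsecv), sd(yn), tolerance = 0.25)
  # deterministic given the seed
  expect_identical(choose_components(Xn, yn, 5, 6, seed = 9),
                   choose_components(Xn, yn, 5, 6, seed = 9))
})

test_that("assessment metrics follow their defining formulas", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r_squared(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_error(r_squared(c(2, 2), c(1, 2)), "zero variance")

  # calibration: residuals (1,-1) with Ic=4, f=1 -> sqrt(2 / 2) = 1
  expect_equal(rmse_metric(c(0, 0, 1, 2), c(1, -1, 1, 2), "calibration", f = 1), 1)
  expect_equal(rmse_metric(c(1, 2), c(1, 2), "prediction"), 0)
  expect_equal(rmse_metric(c(0, 0), c(3, 4), "validation"), sqrt(12.5))
  expect_error(rmse_metric(c(0, 0, 1), c(1, -1, 1), "calibration", f = 2),
               "degrees of freedom")

  expect_equal(rpd(1.0, 0.5), 2.0)
  expect_equal(rpd(1.0, 1.0), 1.0)
  expect_warning(expect_equal(rpd(1, 0), Inf), "infinite")

  expect_identical(classify_rpd(1.2), "unacceptable")
  expect_identical(classify_rpd(1.4), "fair")
  expect_identical(classify_rpd(1.9), "good")
  expect_identical(classify_rpd(2.2), "very_good")
  expect_identical(classify_rpd(2.5), "excellent")
  expect_identical(classify_rpd(3.19), "excellent")
})

test_that("nested five-fold experiments are deterministic and exact in the noise-free limit", {
  cfg <- linear_map_config(seed = 5, som_levels = som_study_levels(12),
                           moisture_levels = c(0, 10, 17),
                           grid = seq(400, 2450, by = 10))
  cfg$noise_sd <- 0; cfg$noise_sd_blue <- 0
  st <- generate_study(cfg)
  m <- suppressWarnings(run_experiment(st, experiment_bandset("A"), seed = 2))
  expect_gt(m$r2_p, 0.999)
  expect_lt(m$rmsep, 1e-3)
  # same seed twice -> identical metrics; pooled R2p invariant to fold labels
  m2 <- suppressWarnings(run_experiment(st, experiment_bandset("A"), seed = 2))
  expect_equal(as.data.frame(m), as.data.frame(m2))
  expect_equal(m$rpd, m$sd_reference / m$rmsep, tolerance = 1e-12)
  expect_error(run_experiment(st, experiment_bandset("A"), folds = 99),
               "fewer samples")
  nosom <- spectrum_set(st$wavelength, st$absorbance,
                        moisture_pct = st$moisture_pct)
  expect_error(run_experiment(nosom, experiment_bandset("A")), "som_pct")
})

test_that("RPD degrades monotonically as reference noise grows", {
  cfg <- linear_map_config(seed = 6, som_levels = som_study_levels(15),
                           moisture_levels = c(0, 10, 17),
                           grid = seq(400, 2450, by = 10))
  st <- generate_study(cfg)
  rpds <- sapply(seq_along(sig <- c(0, 0.25, 0.5, 1, 2)), function(i) {
    set.seed(100 + i)
    noisy <- spectrum_set(st$wavelength, st$absorbance,
                          sample_ids = st$sample_ids,
                          som_pct = pmax(st$som_pct + rnorm(n_samples(st), 0, sig[i]), 0),
                          moisture_pct = st$moisture_pct)
    suppressWarnings(run_experiment(noisy, experiment_bandset("A"), seed = 3))$rpd
  })
  expect_true(all(diff(rpds) < 0))
})
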