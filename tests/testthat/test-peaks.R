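map_from_diag <- function(wavelength, d) {
  structure(list(wavelength = wavelength, values = diag(d),
                 n_perturbations = 5L, perturbation_name = "moisture",
                 normalization = "1/(m-1)"), class = "synchronous_map")
}

test_that("diagonal strength reads X(v, v)", {
  s <- spectrum_set(c(500, 501), rbind(c(0, 2), c(2, 4)),
                    moisture_pct = c(0, 17))
  m <- synchronous_map(dynamic_spectra(s))
  expect_equal(unname(diagonal_strength(m)), c(2, 2))
  s3 <- spectrum_set(c(500, 501), cbind(c(-2, 0, 2), c(1, 0, -1)),
                     moisture_pct = 1:3)
  expect_equal(unname(diagonal_strength(synchronous_map(dynamic_spectra(s3)))),
               c(4, 1))
  z <- map_from_diag(1:4, rep(0, 4))
  expect_equal(unname(diagonal_strength(z)), rep(0, 4))
})

test_that("auto-peak detection finds planted maxima, with scale invariance", {
  w <- seq(1800, 2050)
  bump <- 0.02 * exp(-(w - 1934)^2 / (2 * 15^2))
  m <- map_from_diag(w, bump)
  pk <- detect_auto_peaks(m)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$wavelength, 1934, tolerance = 1)
  expect_equal(pk$strength, max(bump))

  # flat zero diagonal -> empty, not an error
  expect_equal(nrow(detect_auto_peaks(map_from_diag(w, rep(0, length(w))))), 0L)

  # relative prominence: multiplying the map by c > 0 changes nothing
  two <- 0.02 * exp(-(w - 1900)^2 / 200) + 0.01 * exp(-(w - 2000)^2 / 200) +
    0.0003 * sin(w / 3)
  m2 <- map_from_diag(w, two)
  pk2 <- detect_auto_peaks(m2)
  m2s <- m2; m2s$values <- m2$values * 137
  pk2s <- detect_auto_peaks(m2s)
  expect_equal(pk2s$wavelength, pk2$wavelength)
  expect_equal(pk2s$strength, 137 * pk2$strength)

  # every reported peak is a local maximum of the diagonal
  d <- diagonal_strength(m2)
  for (pw in pk2$wavelength) {
    i <- match(pw, w)
    expect_true(d[i] >= d[i - 1] && d[i] >= d[i + 1])
  }

  # min_separation thins close maxima, keeping the stronger one
  twin <- 0.02 * exp(-(w - 1900)^2 / 200) + 0.015 * exp(-(w - 1910)^2 / 200)
  pk3 <- detect_auto_peaks(map_from_diag(w, twin), min_separation = 30)
  expect_equal(nrow(pk3), 1L)
  expect_error(detect_auto_peaks(m, min_prominence_frac = 0), "prominence")
})

test_that("cross-peak signs encode co- and counter-varying bands", {
  # band pair increasing together across the perturbation -> positive
  p <- 1:5
  s <- spectrum_set(c(600, 700, 800),
                    cbind(0.1 * p, 0.05 * p, -0.03 * p) + 1,
                    moisture_pct = p)
  m <- synchronous_map(dynamic_spectra(s))
  expect_identical(cross_peak_sign(m, 600, 700)$sign, "positive")
  expect_identical(cross_peak_sign(m, 600, 800)$sign, "negative")
  # hand case: X12 = -2
  s3 <- spectrum_set(c(500, 501), cbind(c(-2, 0, 2), c(1, 0, -1)),
                     moisture_pct = 1:3)
  cp <- cross_peak_sign(synchronous_map(dynamic_spectra(s3)), 500, 501)
  expect_equal(cp$value, -2)
  expect_identical(cp$sign, "negative")
  # tolerance dead-band and errors
  expect_identical(cross_peak_sign(m, 600, 800, tol = 1)$sign, "null")
  expect_error(cross_peak_sign(m, 600, 601), "not on the map grid")
  expect_error(cross_peak_sign(m, 600, 600), "distinct")
})

test_that("percent change matches the printed-value arithmetic", {
  expect_equal(percent_change(0.1104, 0.0122), -88.9493, tolerance = 1e-4)
  expect_equal(percent_change(0.0054, 0.0299), 453.7037, tolerance = 1e-4)
  expect_equal(percent_change(3.7, 3.7), 0)
  expect_error(percent_change(0, 1), "undefined")
})

test_that("grouped correlation tables replicate the two-perturbation workflow", {
  st <- toy_study()
  tab <- correlation_strength_table(st, "moisture", group_by = "som",
                                    min_separation = 2)
  expect_true(all(c("group_label", "wavelength_nm", "strength") %in% names(tab)))
  expect_identical(attr(tab, "perturbation_name"), "moisture")
  # within each group, peaks are sorted by wavelength
  for (g in unique(tab$group_label)) {
    expect_false(is.unsorted(tab$wavelength_nm[tab$group_label == g]))
  }
  # a group with a single perturbation level is skipped with a warning
  one <- spectrum_set(1:6, matrix(rnorm(12), 2, 6),
                      som_pct = c(1, 1), moisture_pct = c(5, 5))
  expect_warning(res <- correlation_strength_table(one, "moisture", "som"),
                 "skipped")
  expect_equal(nrow(res), 0L)
})
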