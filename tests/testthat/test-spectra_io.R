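test_that("spectra tables parse, validate and round-trip", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "spec.csv")
  writeLines(c("wavelength_nm,a", "400,0.1", "401,0.2", "402,0.3"), f)
  s <- read_spectra_table(f)
  expect_s3_class(s, "spectrum_set")
  expect_equal(n_samples(s), 1L)
  expect_equal(s$wavelength, c(400, 401, 402))
  expect_equal(unname(s$absorbance[1, ]), c(0.1, 0.2, 0.3))

  writeLines(c("wavelength_nm,a", "402,0.1", "401,0.2", "400,0.3"), f)
  expect_error(read_spectra_table(f), "strictly increasing")

  # round-trip at full precision, with metadata join
  set.seed(11)
  s2 <- spectrum_set(400:409, matrix(rnorm(30), nrow = 3),
                     sample_ids = c("x", "y", "z"),
                     som_pct = c(1.5, 2.5, 3.5), moisture_pct = c(0, 5, 17))
  f2 <- file.path(dir, "rt.csv"); fm <- file.path(dir, "rt_meta.csv")
  write_spectra_table(s2, f2, metadata_path = fm)
  expect_identical(readLines(f2, n = 1), "wavelength_nm,x,y,z")
  s3 <- read_spectra_table(f2, metadata_path = fm)
  expect_equal(s3$absorbance, s2$absorbance, tolerance = 1e-12)
  expect_identical(s3$sample_ids, s2$sample_ids)
  expect_equal(s3$som_pct, s2$som_pct)
  expect_equal(s3$moisture_pct, s2$moisture_pct)

  # metadata id that is not in the spectra is a reported error
  writeLines(c("sample_id,som_pct", "nope,1.0"), fm)
  expect_error(read_spectra_table(f2, metadata_path = fm), "missing-metadata")

  # empty sample list still writes the wavelength column
  s0 <- spectrum_set(400:402, matrix(numeric(0), nrow = 0, ncol = 3))
  f0 <- file.path(dir, "empty.csv")
  write_spectra_table(s0, f0)
  expect_identical(readLines(f0, n = 1), "wavelength_nm")
})

test_that("trimming keeps inclusive bounds and is idempotent", {
  s <- spectrum_set(seq(350, 2500), matrix(runif(2151), nrow = 1))
  t1 <- trim_wavelengths(s, 400, 2450)
  expect_equal(length(t1$wavelength), 2051L)
  expect_equal(range(t1$wavelength), c(400, 2450))
  t2 <- trim_wavelengths(t1, 400, 2450)
  expect_identical(t2$absorbance, t1$absorbance)
  expect_equal(length(trim_wavelengths(s, 500, 500)$wavelength), 1L)
  expect_error(trim_wavelengths(s, 10, 20), "empty")
})

test_that("splice correction removes a constructed step and only the step", {
  w <- seq(990, 1010)
  line <- 0.2 + 0.001 * (w - 990)
  step <- line + 0.05 * (w > 1000)
  s <- spectrum_set(w, rbind(step, line))
  out <- splice_correct(s, junction = 1000)
  # stepped sample is restored to the line
  expect_lt(max(abs(out$absorbance[1, ] - line)), 1e-9)
  # continuous sample is untouched within rounding
  expect_lt(max(abs(out$absorbance[2, ] - line)), 1e-12)
  # segment at or below the junction is bit-identical
  expect_identical(out$absorbance[, w <= 1000], s$absorbance[, w <= 1000])

  # minimal two-point-per-side case: offset equals the constructed step
  w4 <- c(999, 1000, 1001, 1002)
  y4 <- c(1, 2, 3 + 0.7, 4 + 0.7)  # slope 1 line with +0.7 step
  s4 <- spectrum_set(w4, matrix(y4, nrow = 1))
  out4 <- splice_correct(s4, 1000)
  expect_equal(unname(out4$absorbance[1, ]), c(1, 2, 3, 4), tolerance = 1e-9)
  expect_error(splice_correct(spectrum_set(c(999, 1000, 1001), matrix(1:3, 1)), 1000),
               "cannot correct")
})

test_that("replicate averaging is a grouped mean and commutes with trimming", {
  w <- 400:419
  reps <- spectrum_set(w, matrix(rep(c(0, 2, 1, 1, 5, 7), each = 20),
                                 nrow = 6, byrow = TRUE),
                       sample_ids = paste0("r", 1:6))
  group <- setNames(rep(c("A", "B", "C"), each = 2), paste0("r", 1:6))
  avg <- average_replicates(reps, group)
  expect_identical(avg$sample_ids, c("A", "B", "C"))
  expect_equal(unname(avg$absorbance[, 1]), c(1, 1, 6))
  # idempotent mean: identical replicates average to themselves
  same <- spectrum_set(w, matrix(0.3, nrow = 9, ncol = 20),
                       sample_ids = paste0("q", 1:9))
  g9 <- setNames(rep("S", 9), paste0("q", 1:9))
  expect_equal(unname(average_replicates(same, g9)$absorbance[1, ]),
               rep(0.3, 20))
  # commutes with trim_wavelengths
  a <- trim_wavelengths(average_replicates(reps, group), 405, 410)
  b <- average_replicates(trim_wavelengths(reps, 405, 410), group)
  expect_equal(a$absorbance, b$absorbance)
  # errors
  expect_error(average_replicates(reps, setNames(character(0), character(0))),
               "empty")
  mism <- spectrum_set(500:519, matrix(1, 1, 20), sample_ids = "m1")
  expect_error(average_replicates(list(reps, mism), c(group, m1 = "A")),
               "grid mismatch")
})

test_that("reflectance converts by log10(1/R) with domain checks", {
  s <- spectrum_set(1:3, matrix(c(1, 0.1, 0.5), nrow = 1))
  a <- reflectance_to_absorbance(s)
  expect_equal(unname(a$absorbance[1, ]), c(0, 1, log10(2)))
  expect_error(reflectance_to_absorbance(
    spectrum_set(1:2, matrix(c(0, 0.5), 1))), "reflectance")
  expect_error(reflectance_to_absorbance(
    spectrum_set(1:2, matrix(c(1.2, 0.5), 1))), "reflectance")
})
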