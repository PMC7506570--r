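#' Reference spectrum of a perturbation series
#'
#' The perturbation-averaged spectrum: the unweighted arithmetic mean over
#' samples at every band, the discrete counterpart of averaging the spectrum
#' over the observed perturbation interval.
#'
#' @param s A [spectrum_set] with at least two samples.
#' @param perturbation_name `"moisture"` or `"som"`; checked for presence so
#'   that a series without perturbation metadata fails early.
#' @return Numeric vector over the grid.
#' @export
reference_spectrum <- function(s, perturbation_name = "moisture") {
  if (n_samples(s) < 2L) stop("insufficient data: need at least 2 samples")
  perturbation_values(s, perturbation_name)
  colMeans(s$absorbance)
}

#' Dynamic spectra under a perturbation
#'
#' Subtracts the reference spectrum from every sample, producing the
#' mean-centered dynamic spectra whose band-to-band covariance defines the
#' synchronous correlation map. Rows are ordered by ascending perturbation
#' value (ties keep input order).
#'
#' @inheritParams reference_spectrum
#' @return An object of class `dynamic_spectra`: list with `wavelength`,
#'   `reference`, `dynamic` (samples x bands, column means zero),
#'   `perturbation`, `perturbation_name`, `p_min`, `p_max`, `sample_ids`.
#' @export
dynamic_spectra <- function(s, perturbation_name = "moisture") {
  if (n_samples(s) < 2L) stop("insufficient data: need at least 2 samples")
  p <- perturbation_values(s, perturbation_name)
  ref <- colMeans(s$absorbance)
  ord <- order(p)
  dyn <- sweep(s$absorbance[ord, , drop = FALSE], 2, ref)
  structure(list(wavelength = s$wavelength, reference = ref, dynamic = dyn,
                 perturbation = p[ord], perturbation_name = perturbation_name,
                 p_min = min(p), p_max = max(p),
                 sample_ids = s$sample_ids[ord]),
            class = "dynamic_spectra")
}

#' Synchronous two-dimensional correlation map
#'
#' The synchronous map X(v1, v2) is the covariance, across the perturbation
#' series, between the dynamic intensities at two wavelengths:
#' X(v1, v2) = 1/(m - 1) * sum_j ydyn(v1, p_j) * ydyn(v2, p_j).
#' It is symmetric, positive semidefinite, and its diagonal (the auto-power
#' spectrum) is non-negative. The 1/(m - 1) sample-covariance normalisation is
#' recorded in the `normalization` field.
#'
#' @param d A [dynamic_spectra] object with at least 2 rows.
#' @return An object of class `synchronous_map`: list with `wavelength`,
#'   `values` (square matrix, absorbance^2), `n_perturbations`,
#'   `perturbation_name`, `normalization`.
#' @export
synchronous_map <- function(d) {
  m <- nrow(d$dynamic)
  if (is.null(m) || m < 2L) stop("insufficient data: need at least 2 perturbation rows")
  x <- crossprod(d$dynamic) / (m - 1)
  structure(list(wavelength = d$wavelength, values = x,
                 n_perturbations = m,
                 perturbation_name = d$perturbation_name,
                 normalization = "1/(m-1)"),
            class = "synchronous_map")
}

#' @export
print.synchronous_map <- function(x, ...) {
  cat("<synchronous_map> ", length(x$wavelength), " x ", length(x$wavelength),
      " (", x$perturbation_name, " perturbation, m = ", x$n_perturbations,
      ", normalization ", x$normalization, ")\n", sep = "")
  invisible(x)
}
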