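#' Construct a spectrum set
#'
#' A `spectrum_set` holds a wavelength grid together with an absorbance matrix
#' (one row per sample, one column per grid point) and optional per-sample
#' perturbation metadata: soil organic matter (SOM) content and gravimetric
#' moisture content, both in % w/w.
#'
#' @param wavelength Numeric vector of wavelengths in nm, strictly increasing.
#' @param absorbance Numeric matrix, `length(sample_ids)` rows and
#'   `length(wavelength)` columns, in absorbance units. All values finite.
#' @param sample_ids Character vector of unique sample labels. Defaults to the
#'   rownames of `absorbance`, or `"s1"`, `"s2"`, ... when absent.
#' @param som_pct Optional numeric vector of SOM contents (% w/w), one per
#'   sample, non-negative.
#' @param moisture_pct Optional numeric vector of moisture contents (% w/w),
#'   one per sample, non-negative.
#'
#' @return An object of class `spectrum_set`: a list with elements
#'   `wavelength`, `absorbance`, `sample_ids`, `som_pct`, `moisture_pct`.
#' @export
#' @examples
#' s <- spectrum_set(400:402, matrix(1:6 / 10, nrow = 2, byrow = TRUE),
#'                   sample_ids = c("a", "b"), som_pct = c(1.2, 3.4))
#' n_samples(s)
spectrum_set <- function(wavelength, absorbance, sample_ids = NULL,
                         som_pct = NULL, moisture_pct = NULL) {
  wavelength <- as.numeric(wavelength)
  if (is.null(dim(absorbance))) {
    absorbance <- matrix(as.numeric(absorbance), nrow = 1)
  }
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  if (is.null(sample_ids)) {
    sample_ids <- rownames(absorbance)
    if (is.null(sample_ids)) {
      sample_ids <- sprintf("s%d", seq_len(nrow(absorbance)))
    }
  }
  sample_ids <- as.character(sample_ids)

  if (length(wavelength) == 0L) stop("wavelength grid is empty")
  if (any(!is.finite(wavelength))) stop("wavelengths must be finite")
  if (length(wavelength) > 1L && any(diff(wavelength) <= 0)) {
    stop("wavelength grid must be strictly increasing")
  }
  if (ncol(absorbance) != length(wavelength)) {
    stop("absorbance has ", ncol(absorbance), " columns but the grid has ",
         length(wavelength), " points")
  }
  if (nrow(absorbance) != length(sample_ids)) {
    stop("absorbance has ", nrow(absorbance), " rows but there are ",
         length(sample_ids), " sample ids")
  }
  if (anyDuplicated(sample_ids)) stop("duplicate sample id: ",
                                      sample_ids[duplicated(sample_ids)][1L])
  if (any(!is.finite(absorbance))) stop("absorbance values must be finite")
  for (nm in c("som_pct", "moisture_pct")) {
    v <- get(nm)
    if (!is.null(v)) {
      v <- as.numeric(v)
      if (length(v) != length(sample_ids)) {
        stop(nm, " must have one value per sample")
      }
      if (any(v < 0, na.rm = TRUE)) stop(nm, " must be non-negative")
      assign(nm, v)
    }
  }
  rownames(absorbance) <- sample_ids
  colnames(absorbance) <- NULL
  structure(
    list(wavelength = wavelength, absorbance = absorbance,
         sample_ids = sample_ids, som_pct = som_pct,
         moisture_pct = moisture_pct),
    class = "spectrum_set"
  )
}

#' Default 1-nm vis-NIR wavelength grid
#'
#' The working grid after trimming the noisy edges of a 350-2500 nm
#' spectrometer range: 400 to 2450 nm at 1 nm spacing, 2051 points.
#'
#' @param lo,hi Inclusive bounds in nm.
#' @param by Grid spacing in nm.
#' @return Numeric vector of wavelengths.
#' @export
default_grid <- function(lo = 400, hi = 2450, by = 1) seq(lo, hi, by = by)

#' Grid spacing of a spectrum set
#'
#' @param s A `spectrum_set`.
#' @param tol Tolerance on spacing uniformity, in nm.
#' @return The common spacing in nm; errors if the grid is not uniform.
#' @export
grid_spacing <- function(s, tol = 1e-9) {
  w <- s$wavelength
  if (length(w) < 2L) return(NA_real_)
  d <- diff(w)
  if (max(d) - min(d) > tol) stop("wavelength grid is not uniformly spaced")
  d[1L]
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat("<spectrum_set> ", n_samples(x), " sample(s) x ", length(x$wavelength),
      " band(s), ", x$wavelength[1L], "-", x$wavelength[length(x$wavelength)],
      " nm\n", sep = "")
  if (!is.null(x$som_pct)) {
    cat("  som_pct: ", paste(format(utils::head(x$som_pct, 5)), collapse = ", "),
        if (n_samples(x) > 5) ", ..." else "", "\n", sep = "")
  }
  if (!is.null(x$moisture_pct)) {
    cat("  moisture_pct: ",
        paste(format(utils::head(x$moisture_pct, 5)), collapse = ", "),
        if (n_samples(x) > 5) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' Number of samples in a spectrum set
#' @param s A `spectrum_set`.
#' @return Integer count.
#' @export
n_samples <- function(s) nrow(s$absorbance)

# Subset a spectrum_set by sample index, keeping metadata aligned.
subset_samples <- function(s, idx) {
  spectrum_set(s$wavelength, s$absorbance[idx, , drop = FALSE],
               sample_ids = s$sample_ids[idx],
               som_pct = if (!is.null(s$som_pct)) s$som_pct[idx],
               moisture_pct = if (!is.null(s$moisture_pct)) s$moisture_pct[idx])
}

# Fetch a perturbation vector ("moisture" or "som") with a clear error.
perturbation_values <- function(s, perturbation_name) {
  field <- switch(perturbation_name,
                  moisture = "moisture_pct",
                  som = "som_pct",
                  stop("unknown perturbation variable: ", perturbation_name))
  v <- s[[field]]
  if (is.null(v) || any(!is.finite(v))) {
    stop("perturbation metadata '", field, "' is missing or non-finite")
  }
  v
}
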