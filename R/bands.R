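#' Construct a band set
#'
#' An ordered list of disjoint inclusive wavelength intervals selecting the
#' predictor bands for a regression experiment.
#'
#' @param lo,hi Numeric vectors of interval bounds in nm (inclusive),
#'   `lo[i] <= hi[i]`.
#' @param label Optional experiment tag.
#' @return A data frame of class `band_set` with columns `lo`, `hi`, sorted by
#'   `lo`, and attribute `label`.
#' @export
band_set <- function(lo, hi, label = NULL) {
  if (length(lo) != length(hi)) stop("lo and hi must have equal length")
  if (any(lo > hi)) stop("interval with lo > hi")
  ord <- order(lo)
  lo <- lo[ord]; hi <- hi[ord]
  if (length(lo) > 1L && any(lo[-1L] <= hi[-length(hi)])) {
    stop("band intervals must be disjoint")
  }
  structure(data.frame(lo = lo, hi = hi),
            label = label, class = c("band_set", "data.frame"))
}

#' Count grid points covered by a band set
#'
#' The number of grid wavelengths falling inside any interval of the set,
#' endpoints inclusive — the "number of bands" entering a PLSR model.
#'
#' @param b A [band_set].
#' @param grid Numeric wavelength grid (nm), e.g. [default_grid()].
#' @return Integer count.
#' @export
#' @examples
#' count_bands(band_set(400, 2450), default_grid())  # 2051
count_bands <- function(b, grid = default_grid()) {
  sum(vapply(seq_len(nrow(b)),
             function(i) sum(grid >= b$lo[i] & grid <= b$hi[i]), integer(1)))
}

#' Remove open exclusion windows from a full range
#'
#' Complements the exclusion windows within `full`, treating each window as
#' OPEN: only wavelengths strictly between a window's endpoints are dropped,
#' so the window endpoints themselves stay in the retained set. Removing the
#' moisture windows 1396-1498, 1883-1985 and 2159-2261 nm from 400-2450 nm
#' therefore retains 400-1396, 1498-1883, 1985-2159 and 2261-2450 nm.
#'
#' @param full A length-2 numeric `c(lo, hi)` or single-interval [band_set].
#' @param exclusions A [band_set] (or data frame with `lo`/`hi`) of windows,
#'   each contained in `full`.
#' @param label Optional tag for the result.
#' @return A [band_set] of the retained intervals.
#' @export
exclude_windows <- function(full, exclusions, label = NULL) {
  if (is.numeric(full) && length(full) == 2L) full <- band_set(full[1], full[2])
  if (nrow(full) != 1L) stop("full must be a single interval")
  flo <- full$lo; fhi <- full$hi
  if (is.null(exclusions) || nrow(exclusions) == 0L) {
    return(band_set(flo, fhi, label = label))
  }
  if (any(exclusions$lo < flo | exclusions$hi > fhi)) {
    stop("exclusion window outside the full range")
  }
  ord <- order(exclusions$lo)
  elo <- exclusions$lo[ord]; ehi <- exclusions$hi[ord]
  if (length(elo) > 1L && any(elo[-1L] < ehi[-length(ehi)])) {
    stop("exclusion windows must be disjoint")
  }
  lo <- c(flo, ehi)
  hi <- c(elo, fhi)
  band_set(lo, hi, label = label)
}

#' Preset band sets of the four regression experiments
#'
#' * `A` — all bands, 400-2450 nm (2051 points on the 1-nm grid).
#' * `B` — all bands minus the three moisture windows (open windows
#'   1396-1498, 1883-1985, 2159-2261 nm): 1748 points.
#' * `C` — as `B`, additionally dropping the noisy 400-500 nm region (the
#'   retained range starts at 500 nm): 1648 points.
#' * `D` — the SOM-related bands only: 500-697, 1546-1746, 2100-2159 nm,
#'   459 points.
#'
#' @param tag One of `"A"`, `"B"`, `"C"`, `"D"`.
#' @return A [band_set] labelled with the tag.
#' @export
experiment_bandset <- function(tag = c("A", "B", "C", "D")) {
  tag <- match.arg(tag)
  switch(tag,
    A = band_set(400, 2450, label = "A"),
    B = band_set(c(400, 1498, 1985, 2261), c(1396, 1883, 2159, 2450), label = "B"),
    C = band_set(c(500, 1498, 1985, 2261), c(1396, 1883, 2159, 2450), label = "C"),
    D = band_set(c(500, 1546, 2100), c(697, 1746, 2159), label = "D"))
}

#' Restrict a spectrum set to a band set
#'
#' Keeps exactly the grid columns counted by [count_bands()], in wavelength
#' order; sample metadata is unchanged.
#'
#' @param s A [spectrum_set].
#' @param b A [band_set].
#' @return The restricted [spectrum_set].
#' @export
apply_bandset <- function(s, b) {
  keep <- rep(FALSE, length(s$wavelength))
  for (i in seq_len(nrow(b))) {
    keep <- keep | (s$wavelength >= b$lo[i] & s$wavelength <= b$hi[i])
  }
  if (!any(keep)) stop("band set selects no grid points")
  spectrum_set(s$wavelength[keep], s$absorbance[, keep, drop = FALSE],
               sample_ids = s$sample_ids, som_pct = s$som_pct,
               moisture_pct = s$moisture_pct)
}

#' Serialize a band set to JSON
#'
#' @param b A [band_set].
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return The JSON string (list of `[lo, hi]` pairs), invisibly when written.
#' @export
bandset_to_json <- function(b, path = NULL) {
  pairs <- lapply(seq_len(nrow(b)), function(i) c(b$lo[i], b$hi[i]))
  js <- jsonlite::toJSON(pairs, auto_unbox = FALSE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(as.character(js))
}

#' Parse a band-range string
#'
#' Accepts the compact form `"500-1396,1498-1883"` used on command lines.
#'
#' @param txt A single string of comma-separated `lo-hi` ranges.
#' @param label Optional tag.
#' @return A [band_set].
#' @export
parse_bands <- function(txt, label = NULL) {
  parts <- strsplit(trimws(strsplit(txt, ",")[[1L]]), "-")
  lo <- vapply(parts, function(p) as.numeric(p[1L]), numeric(1))
  hi <- vapply(parts, function(p) as.numeric(p[length(p)]), numeric(1))
  band_set(lo, hi, label = label)
}
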