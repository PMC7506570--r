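#' Read a wide-format spectra table
#'
#' Reads a comma-delimited table whose first column is `wavelength_nm` and
#' whose remaining columns are per-sample absorbance values, optionally
#' joining a metadata table keyed by sample id.
#'
#' @param path Path to the spectra CSV.
#' @param metadata_path Optional path to a metadata CSV with columns
#'   `sample_id` and any of `som_pct`, `moisture_pct`.
#' @return A [spectrum_set].
#' @export
read_spectra_table <- function(path, metadata_path = NULL) {
  tab <- utils::read.csv(path, check.names = FALSE)
  if (ncol(tab) < 1L) stop("spectra table has no columns")
  w <- as.numeric(tab[[1L]])
  if (any(!is.finite(w))) stop("non-numeric wavelength column")
  if (length(w) > 1L && any(diff(w) <= 0)) {
    stop("wavelength column must be strictly increasing")
  }
  ids <- colnames(tab)[-1L]
  if (anyDuplicated(ids)) {
    stop("duplicate sample id in spectra table: ", ids[duplicated(ids)][1L])
  }
  a <- if (length(ids)) t(as.matrix(tab[, -1L, drop = FALSE])) else
    matrix(numeric(0), nrow = 0, ncol = length(w))
  som <- moist <- NULL
  if (!is.null(metadata_path)) {
    md <- utils::read.csv(metadata_path)
    if (!"sample_id" %in% names(md)) stop("metadata table needs a sample_id column")
    md$sample_id <- as.character(md$sample_id)
    missing <- setdiff(md$sample_id, ids)
    if (length(missing)) {
      stop("missing-metadata error: metadata ids not present in spectra: ",
           paste(missing, collapse = ", "))
    }
    m <- match(ids, md$sample_id)
    if ("som_pct" %in% names(md)) som <- md$som_pct[m]
    if ("moisture_pct" %in% names(md)) moist <- md$moisture_pct[m]
  }
  spectrum_set(w, a, sample_ids = ids, som_pct = som, moisture_pct = moist)
}

#' Write a wide-format spectra table
#'
#' Writes the inverse of [read_spectra_table()]: a CSV whose header is
#' `wavelength_nm` followed by the sample ids, at full double precision.
#' Metadata, when present, is written alongside as `<path>` with a
#' `_metadata.csv` suffix if `metadata_path` is given.
#'
#' @param s A [spectrum_set].
#' @param path Output CSV path.
#' @param metadata_path Optional path for the sample metadata CSV.
#' @return Invisibly, `path`.
#' @export
write_spectra_table <- function(s, path, metadata_path = NULL) {
  tab <- data.frame(wavelength_nm = s$wavelength, check.names = FALSE)
  for (i in seq_len(n_samples(s))) tab[[s$sample_ids[i]]] <- s$absorbance[i, ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("wavelength_nm", s$sample_ids), collapse = ","), con)
  utils::write.table(format(tab, digits = 17, trim = TRUE, scientific = FALSE),
                     con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  if (!is.null(metadata_path)) {
    md <- data.frame(sample_id = s$sample_ids)
    if (!is.null(s$som_pct)) md$som_pct <- s$som_pct
    if (!is.null(s$moisture_pct)) md$moisture_pct <- s$moisture_pct
    utils::write.csv(md, metadata_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Trim a spectrum set to a wavelength window
#'
#' Discards grid points outside `[lo, hi]` (inclusive). Used to drop the noisy
#' 350-400 nm and 2451-2500 nm edges of the spectrometer range, leaving the
#' 2051-band working grid.
#'
#' @param s A [spectrum_set].
#' @param lo,hi Window bounds in nm, `lo <= hi`.
#' @return The trimmed [spectrum_set]; sample metadata unchanged.
#' @export
trim_wavelengths <- function(s, lo, hi) {
  if (lo > hi) stop("lo must not exceed hi")
  keep <- s$wavelength >= lo & s$wavelength <= hi
  if (!any(keep)) stop("empty result: no grid points in [", lo, ", ", hi, "]")
  spectrum_set(s$wavelength[keep], s$absorbance[, keep, drop = FALSE],
               sample_ids = s$sample_ids, som_pct = s$som_pct,
               moisture_pct = s$moisture_pct)
}

#' Remove a detector-junction step by additive splice correction
#'
#' Field spectrometers that switch detectors mid-range (here at 1000 nm) leave
#' a step discontinuity at the junction. For each sample the segment at
#' wavelengths above the junction is shifted by a constant offset so that its
#' first point equals the value extrapolated linearly from the last two points
#' at or below the junction. The segment at or below the junction is left
#' bit-identical.
#'
#' @param s A [spectrum_set].
#' @param junction Junction wavelength in nm, strictly inside the grid range.
#' @return The corrected [spectrum_set].
#' @export
splice_correct <- function(s, junction = 1000) {
  w <- s$wavelength
  left <- which(w <= junction)
  right <- which(w > junction)
  if (length(left) < 2L || length(right) < 2L) {
    stop("cannot correct: need at least 2 grid points on each side of the junction")
  }
  i1 <- left[length(left) - 1L]; i2 <- left[length(left)]
  j1 <- right[1L]
  a <- s$absorbance
  # linear extrapolation from the last two left-segment points to w[j1]
  slope <- (a[, i2] - a[, i1]) / (w[i2] - w[i1])
  expected <- a[, i2] + slope * (w[j1] - w[i2])
  offset <- expected - a[, j1]
  a[, right] <- a[, right] + offset
  spectrum_set(w, a, sample_ids = s$sample_ids, som_pct = s$som_pct,
               moisture_pct = s$moisture_pct)
}

#' Average replicate spectra into per-sample spectra
#'
#' Each physical sample is typically scanned several times (e.g., three scans
#' at each of three spots); the sample spectrum is the arithmetic mean of its
#' replicates.
#'
#' @param sets A list of [spectrum_set] objects sharing one wavelength grid,
#'   or a single `spectrum_set` whose rows are replicates.
#' @param group Named character vector mapping replicate id to sample id.
#' @return A [spectrum_set] with one row per distinct sample id, in first-seen
#'   order of the group values; metadata is taken from the first replicate of
#'   each group.
#' @export
average_replicates <- function(sets, group) {
  if (inherits(sets, "spectrum_set")) sets <- list(sets)
  if (!length(sets)) stop("empty replicate list")
  w <- sets[[1L]]$wavelength
  for (s in sets[-1L]) {
    if (length(s$wavelength) != length(w) || any(s$wavelength != w)) {
      stop("grid mismatch between replicate sets")
    }
  }
  a <- do.call(rbind, lapply(sets, function(s) s$absorbance))
  ids <- unlist(lapply(sets, function(s) s$sample_ids), use.names = FALSE)
  som <- unlist(lapply(sets, function(s)
    if (is.null(s$som_pct)) rep(NA_real_, n_samples(s)) else s$som_pct))
  moist <- unlist(lapply(sets, function(s)
    if (is.null(s$moisture_pct)) rep(NA_real_, n_samples(s)) else s$moisture_pct))
  if (!length(group)) stop("empty replicate grouping")
  if (is.null(names(group))) stop("group must be named by replicate id")
  miss <- setdiff(ids, names(group))
  if (length(miss)) stop("replicates without a group: ", paste(miss, collapse = ", "))
  sample_of <- group[ids]
  out_ids <- unique(unname(sample_of))
  rows <- t(vapply(out_ids, function(sid) {
    colMeans(a[sample_of == sid, , drop = FALSE])
  }, numeric(length(w))))
  first <- match(out_ids, sample_of)
  som_out <- som[first]; moist_out <- moist[first]
  spectrum_set(w, rows, sample_ids = out_ids,
               som_pct = if (all(is.na(som_out))) NULL else som_out,
               moisture_pct = if (all(is.na(moist_out))) NULL else moist_out)
}

#' Convert reflectance spectra to absorbance
#'
#' Applies the standard apparent-absorbance convention A = log10(1/R)
#' elementwise, for users whose instrument exports reflectance.
#'
#' @param s A [spectrum_set] whose values are reflectances in (0, 1].
#' @return A [spectrum_set] in absorbance units.
#' @export
reflectance_to_absorbance <- function(s) {
  r <- s$absorbance
  if (any(r <= 0) || any(r > 1)) {
    stop("reflectance values must lie in (0, 1]")
  }
  spectrum_set(s$wavelength, log10(1 / r), sample_ids = s$sample_ids,
               som_pct = s$som_pct, moisture_pct = s$moisture_pct)
}
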