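#' Correlation strength along the map diagonal
#'
#' The diagonal X(v, v) of a synchronous map is the variance of the dynamic
#' intensity at each band: the "correlation strength" profile whose local
#' maxima are the auto-peaks.
#'
#' @param map A [synchronous_map].
#' @return Named numeric vector (names = wavelengths in nm), absorbance^2.
#' @export
diagonal_strength <- function(map) {
  d <- diag(map$values)
  names(d) <- map$wavelength
  d
}

# Topographic prominence of local maxima of y: for each peak, the drop from
# its height to the higher of the two key saddles separating it from higher
# terrain (for the global maximum: height minus the global minimum).
peak_prominences <- function(y, idx) {
  vapply(idx, function(i) {
    h <- y[i]
    left <- y[seq_len(i - 1L)]
    right <- if (i < length(y)) y[(i + 1L):length(y)] else numeric()
    saddle <- function(seg, from_end) {
      if (!length(seg)) return(NA_real_)
      if (from_end) seg <- rev(seg)      # walk outward from the peak
      higher <- which(seg > h)
      if (!length(higher)) return(NA_real_)
      min(seg[seq_len(higher[1L])])
    }
    sl <- saddle(left, from_end = TRUE)
    sr <- saddle(right, from_end = FALSE)
    key <- if (is.na(sl) && is.na(sr)) min(y) else max(sl, sr, na.rm = TRUE)
    h - key
  }, numeric(1))
}

#' Detect auto-peaks on the synchronous-map diagonal
#'
#' Local maxima of the diagonal whose topographic prominence is at least
#' `min_prominence_frac` times the diagonal maximum, thinned so that no two
#' reported peaks lie closer than `min_separation` nm (the stronger peak
#' wins). The relative prominence rule makes detection invariant to overall
#' scaling of the map.
#'
#' @param map A [synchronous_map].
#' @param min_prominence_frac Fraction of the diagonal maximum, in (0, 1].
#' @param min_separation Minimum spacing between reported peaks, nm.
#' @return A data frame with columns `wavelength`, `strength` (the diagonal
#'   value) and `prominence`, sorted by wavelength. Empty for a flat-zero
#'   diagonal.
#' @export
detect_auto_peaks <- function(map, min_prominence_frac = 0.05,
                              min_separation = 20) {
  if (min_prominence_frac <= 0 || min_prominence_frac > 1) {
    stop("min_prominence_frac must be in (0, 1]")
  }
  y <- diag(map$values)
  w <- map$wavelength
  empty <- data.frame(wavelength = numeric(), strength = numeric(),
                      prominence = numeric())
  if (length(y) < 3L || max(y) <= 0) return(empty)
  interior <- 2:(length(y) - 1L)
  is_max <- y[interior] > y[interior - 1L] & y[interior] >= y[interior + 1L]
  idx <- interior[is_max]
  if (!length(idx)) return(empty)
  prom <- peak_prominences(y, idx)
  keep <- prom >= min_prominence_frac * max(y)
  idx <- idx[keep]; prom <- prom[keep]
  if (!length(idx)) return(empty)
  # thin by minimum separation, strongest first
  ord <- order(y[idx], decreasing = TRUE)
  kept <- integer()
  for (i in ord) {
    if (!length(kept) || all(abs(w[idx[kept]] - w[idx[i]]) >= min_separation)) {
      kept <- c(kept, i)
    }
  }
  kept <- kept[order(w[idx[kept]])]
  data.frame(wavelength = w[idx[kept]], strength = unname(y[idx[kept]]),
             prominence = unname(prom[kept]))
}

#' Sign of a cross-peak
#'
#' Reads the synchronous map at an off-diagonal coordinate pair. A positive
#' sign means the intensities at the two bands move together across the
#' perturbation series; a negative sign means they move in opposite
#' directions; `null` means |X| does not exceed `tol`.
#'
#' @param map A [synchronous_map].
#' @param w1,w2 Wavelengths in nm, both on the grid, `w1 != w2`.
#' @param tol Dead-band in absorbance^2 below which the sign is `null`.
#' @return A data frame row: `wavelength_1`, `wavelength_2`, `value`, `sign`.
#' @export
cross_peak_sign <- function(map, w1, w2, tol = 0) {
  i <- match(w1, map$wavelength)
  j <- match(w2, map$wavelength)
  if (is.na(i) || is.na(j)) stop("wavelength not on the map grid")
  if (w1 == w2) stop("cross-peak needs two distinct wavelengths")
  v <- map$values[i, j]
  s <- if (v > tol) "positive" else if (v < -tol) "negative" else "null"
  data.frame(wavelength_1 = w1, wavelength_2 = w2, value = v, sign = s)
}

#' Per-group auto-peak correlation-strength tables
#'
#' Reproduces the tabulated 2D-COS workflow for a two-perturbation study:
#' hold one variable fixed (group by it), treat the other as the perturbation,
#' and for each group compute the synchronous map and its detected auto-peaks.
#'
#' @param study A [spectrum_set] with both metadata columns present.
#' @param perturbation_name Variable treated as the perturbation
#'   (`"moisture"` or `"som"`).
#' @param group_by Variable held fixed within each group (the other one).
#' @param group_digits Groups are formed by exact match after rounding the
#'   held-fixed variable to this many digits.
#' @param min_prominence_frac,min_separation Passed to [detect_auto_peaks()].
#' @return A data frame with columns `group_label` (held-fixed value),
#'   `wavelength_nm`, `strength`, sorted by group then wavelength. Groups with
#'   fewer than two distinct perturbation levels are skipped with a warning.
#'   The perturbation name is attached as attribute `perturbation_name`.
#' @export
correlation_strength_table <- function(study, perturbation_name = "moisture",
                                       group_by = "som", group_digits = 2,
                                       min_prominence_frac = 0.05,
                                       min_separation = 20) {
  g <- round(perturbation_values(study, group_by), group_digits)
  out <- list()
  for (lev in sort(unique(g))) {
    idx <- which(g == lev)
    sub <- subset_samples(study, idx)
    p <- perturbation_values(sub, perturbation_name)
    if (length(unique(p)) < 2L) {
      warning("group ", group_by, " = ", lev,
              " has fewer than 2 perturbation levels; skipped")
      next
    }
    peaks <- detect_auto_peaks(synchronous_map(dynamic_spectra(sub, perturbation_name)),
                               min_prominence_frac, min_separation)
    if (nrow(peaks)) {
      out[[length(out) + 1L]] <- data.frame(group_label = lev,
                                            wavelength_nm = peaks$wavelength,
                                            strength = peaks$strength)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(group_label = numeric(), wavelength_nm = numeric(),
               strength = numeric())
  attr(res, "perturbation_name") <- perturbation_name
  res
}

#' Relative change between two values, in percent
#'
#' `100 * (v_to - v_from) / v_from`; the convention behind statements such as
#' "an x% reduction of correlation strength" or "an x% RPD improvement".
#'
#' @param v_from Baseline value, non-zero.
#' @param v_to New value.
#' @return Percent change (negative for a reduction).
#' @export
percent_change <- function(v_from, v_to) {
  if (any(v_from == 0)) stop("percent change from 0 is undefined")
  100 * (v_to - v_from) / v_from
}
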