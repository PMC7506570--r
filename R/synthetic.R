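#' Gravimetric moisture dosing
#'
#' Mass moisture content of a dosed sample: theta_m = 100 * Mw / Ms, where Mw
#' is the mass of added water and Ms the oven-dry soil mass.
#'
#' @param water_mass Water mass in g, `>= 0`.
#' @param dry_soil_mass Oven-dry soil mass in g, `> 0`.
#' @return A list with `water_mass`, `dry_soil_mass` and `theta_m` (% w/w).
#' @export
#' @examples
#' dose_moisture(17, 100)$theta_m  # 17
dose_moisture <- function(water_mass, dry_soil_mass) {
  if (dry_soil_mass <= 0) stop("dry_soil_mass must be positive")
  if (water_mass < 0) stop("water_mass must be non-negative")
  list(water_mass = water_mass, dry_soil_mass = dry_soil_mass,
       theta_m = 100 * water_mass / dry_soil_mass)
}

#' Specify one Gaussian absorption feature
#'
#' Each feature is a Gaussian line whose amplitude and center respond to the
#' two perturbation variables:
#' amplitude(som, m) = amp0 + amp_per_moisture * m * qs(som) +
#'                     amp_per_som * som * qm(m),
#' center(m) = center0 + shift_per_moisture * m,
#' with qm(m) = 1 / (1 + m / quench_moisture) modelling the quenching of weak
#' SOM features by water, and qs(som) = 1 / (1 + som / quench_som) modelling
#' the attenuation of the apparent moisture response in organic-rich soil.
#' Either quench factor is 1 when the corresponding parameter is `NA`.
#'
#' @param center0 Center at zero moisture, nm.
#' @param width Gaussian sigma, nm, `> 0`.
#' @param amp0 Perturbation-independent amplitude, absorbance.
#' @param amp_per_moisture Amplitude response, absorbance per % moisture.
#' @param amp_per_som Amplitude response, absorbance per % SOM.
#' @param shift_per_moisture Center red-shift, nm per % moisture.
#' @param quench_moisture Moisture (% w/w) at which the SOM amplitude term is
#'   halved, or `NA` for no quenching.
#' @param quench_som SOM (% w/w) at which the moisture amplitude term is
#'   halved, or `NA` for no attenuation.
#' @return A list of class `peak_spec`.
#' @export
peak_spec <- function(center0, width, amp0 = 0, amp_per_moisture = 0,
                      amp_per_som = 0, shift_per_moisture = 0,
                      quench_moisture = NA_real_, quench_som = NA_real_) {
  if (width <= 0) stop("width must be positive")
  stopifnot(is.finite(amp0), is.finite(amp_per_moisture), is.finite(amp_per_som))
  structure(list(center0 = center0, width = width, amp0 = amp0,
                 amp_per_moisture = amp_per_moisture,
                 amp_per_som = amp_per_som,
                 shift_per_moisture = shift_per_moisture,
                 quench_moisture = quench_moisture,
                 quench_som = quench_som),
            class = "peak_spec")
}

#' Default synthetic-study configuration
#'
#' Encodes the spectral phenomenology of moist loam soil in the vis-NIR:
#' two dominant water absorption peaks near 1410 and 1906 nm that grow and
#' red-shift with moisture (reaching roughly 1453 and 1928 nm at 17% w/w),
#' a weakly moisture-sensitive mineral hump at 2210 nm, three weak SOM
#' features at 597 nm (broad, ~100 nm full width at half maximum), 1646 nm
#' and 2138 nm that are quenched by moisture, an overall darkening of the
#' baseline with moisture, and elevated sensor noise between 400 and 500 nm.
#' The apparent moisture response attenuates with increasing SOM
#' (`quench_som`), reproducing the observed collapse of moisture-driven
#' correlation strength in organic-rich samples.
#'
#' @param seed Integer seed for the noise stream.
#' @param som_levels SOM levels (% w/w) of the study design. Defaults to the
#'   six category values 0.40, 1.12, 2.12, 3.35, 4.51, 7.92.
#' @param moisture_levels Moisture dosing levels (% w/w); defaults to
#'   oven-dry, 5, 10, 15, 17.
#' @param noise_sd Gaussian noise sd, absorbance.
#' @param noise_sd_blue Extra noise sd (added in quadrature) for 400-500 nm.
#' @param grid Wavelength grid, nm.
#' @return A list of class `synthetic_config`.
#' @export
default_synthetic_config <- function(seed = 1L,
                                     som_levels = c(0.40, 1.12, 2.12, 3.35, 4.51, 7.92),
                                     moisture_levels = c(0, 5, 10, 15, 17),
                                     noise_sd = 0.003,
                                     noise_sd_blue = 0.01,
                                     grid = default_grid()) {
  peaks <- list(
    water_1410 = peak_spec(1410, 35, amp0 = 0.05, amp_per_moisture = 0.016,
                           shift_per_moisture = 2.5, quench_som = 3.3),
    water_1906 = peak_spec(1906, 45, amp0 = 0.08, amp_per_moisture = 0.024,
                           shift_per_moisture = 1.3, quench_som = 3.3),
    mineral_2210 = peak_spec(2210, 26, amp0 = 0.08, amp_per_moisture = 0.005),
    som_597 = peak_spec(597, 42.5, amp_per_som = 0.020, quench_moisture = 1),
    som_1646 = peak_spec(1646, 25, amp_per_som = 0.012, quench_moisture = 1),
    som_2138 = peak_spec(2138, 22, amp_per_som = 0.008, quench_moisture = 1)
  )
  synthetic_config(grid = grid, peaks = peaks, baseline_offset = 0.30,
                   baseline_slope = 1e-4, darkening_per_moisture = 0.005,
                   noise_sd = noise_sd, noise_sd_blue = noise_sd_blue,
                   seed = seed, som_levels = som_levels,
                   moisture_levels = moisture_levels)
}

#' Assemble a synthetic-study configuration
#'
#' @param grid Wavelength grid, nm.
#' @param peaks List of [peak_spec] objects.
#' @param baseline_offset Baseline absorbance at 400 nm.
#' @param baseline_slope Baseline slope, absorbance per nm.
#' @param darkening_per_moisture Flat absorbance increase per % moisture.
#' @param noise_sd,noise_sd_blue Noise sds in absorbance (`_blue` applies to
#'   400-500 nm, added in quadrature); both `>= 0`.
#' @param seed Integer seed.
#' @param som_levels,moisture_levels Study design levels (% w/w), non-negative.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(grid, peaks, baseline_offset = 0,
                             baseline_slope = 0, darkening_per_moisture = 0,
                             noise_sd = 0, noise_sd_blue = 0, seed = 1L,
                             som_levels = numeric(), moisture_levels = numeric()) {
  if (noise_sd < 0 || noise_sd_blue < 0) stop("noise sds must be non-negative")
  if (any(som_levels < 0) || any(moisture_levels < 0)) {
    stop("study levels must be non-negative")
  }
  structure(list(grid = as.numeric(grid), peaks = peaks,
                 baseline_offset = baseline_offset,
                 baseline_slope = baseline_slope,
                 darkening_per_moisture = darkening_per_moisture,
                 noise_sd = noise_sd, noise_sd_blue = noise_sd_blue,
                 seed = as.integer(seed), som_levels = as.numeric(som_levels),
                 moisture_levels = as.numeric(moisture_levels)),
            class = "synthetic_config")
}

#' Read a synthetic-study configuration from YAML
#'
#' The YAML mirrors [synthetic_config()] field for field; peaks are a named
#' map of [peak_spec()] argument lists.
#'
#' @param path Path to a YAML file.
#' @return A `synthetic_config`.
#' @export
read_synthetic_config <- function(path) {
  y <- yaml::read_yaml(path)
  peaks <- lapply(y$peaks, function(p) do.call(peak_spec, p))
  grid <- if (is.null(y$grid)) default_grid() else
    seq(y$grid$lo, y$grid$hi, by = if (is.null(y$grid$by)) 1 else y$grid$by)
  args <- y[setdiff(names(y), c("peaks", "grid"))]
  do.call(synthetic_config, c(list(grid = grid, peaks = peaks), args))
}

#' Noise-free rendered spectrum
#'
#' The deterministic part of the generative model, useful as a closed-form
#' oracle: baseline + moisture darkening + sum of Gaussian features.
#'
#' @param cfg A `synthetic_config`.
#' @param som SOM content, % w/w.
#' @param moisture Moisture content, % w/w.
#' @return Numeric absorbance vector over `cfg$grid`.
#' @export
noiseless_spectrum <- function(cfg, som, moisture) {
  w <- cfg$grid
  a <- cfg$baseline_offset + cfg$baseline_slope * (w - 400) +
    cfg$darkening_per_moisture * moisture
  for (p in cfg$peaks) {
    qm <- if (is.finite(p$quench_moisture)) 1 / (1 + moisture / p$quench_moisture) else 1
    qs <- if (is.finite(p$quench_som)) 1 / (1 + som / p$quench_som) else 1
    amp <- p$amp0 + p$amp_per_moisture * moisture * qs + p$amp_per_som * som * qm
    center <- p$center0 + p$shift_per_moisture * moisture
    a <- a + amp * exp(-(w - center)^2 / (2 * p$width^2))
  }
  a
}

#' Generate one synthetic soil spectrum
#'
#' Draws Gaussian noise from the current RNG stream on top of
#' [noiseless_spectrum()]; the 400-500 nm region receives extra noise added
#' in quadrature, emulating the low quantum efficiency of vis sensors there.
#'
#' @inheritParams noiseless_spectrum
#' @param id Sample id for the returned one-row set.
#' @return A one-sample [spectrum_set] with metadata filled in.
#' @export
generate_soil_spectrum <- function(cfg, som, moisture, id = "synthetic") {
  if (som < 0 || moisture < 0) stop("som and moisture must be non-negative")
  w <- cfg$grid
  sd_eff <- rep(cfg$noise_sd, length(w))
  blue <- w >= 400 & w <= 500
  sd_eff[blue] <- sqrt(cfg$noise_sd^2 + cfg$noise_sd_blue^2)
  a <- noiseless_spectrum(cfg, som, moisture) +
    stats::rnorm(length(w), 0, sd_eff)
  spectrum_set(w, matrix(a, nrow = 1), sample_ids = id,
               som_pct = som, moisture_pct = moisture)
}

#' Generate a full synthetic dosing study
#'
#' One sample per (SOM level, moisture level) pair of the design cross
#' product, emulating a set of field samples each dosed at every moisture
#' level. Reproducible from `cfg$seed`.
#'
#' @param cfg A `synthetic_config` with non-empty `som_levels` and
#'   `moisture_levels`.
#' @return A [spectrum_set] with `length(som_levels) * length(moisture_levels)`
#'   samples; ids encode both levels.
#' @export
generate_study <- function(cfg) {
  if (!length(cfg$som_levels) || !length(cfg$moisture_levels)) {
    stop("som_levels and moisture_levels must be non-empty")
  }
  design <- expand.grid(moisture = cfg$moisture_levels, som = cfg$som_levels,
                        KEEP.OUT.ATTRS = FALSE)
  set.seed(cfg$seed)
  rows <- matrix(NA_real_, nrow(design), length(cfg$grid))
  for (i in seq_len(nrow(design))) {
    rows[i, ] <- generate_soil_spectrum(cfg, design$som[i],
                                        design$moisture[i])$absorbance
  }
  ids <- sprintf("som%0.2f_m%02g_%03d", design$som, design$moisture,
                 seq_len(nrow(design)))
  spectrum_set(cfg$grid, rows, sample_ids = ids, som_pct = design$som,
               moisture_pct = design$moisture)
}

#' Planted auto-peak positions of a synthetic configuration
#'
#' The noise-free ground truth for peak-recovery checks: renders the study
#' design without noise for one group (one held-fixed value), runs the
#' synchronous correlation analysis, and returns the detected auto-peaks.
#' Because no noise is involved, these positions are a deterministic function
#' of the configuration.
#'
#' @param cfg A `synthetic_config`.
#' @param perturbation_name `"moisture"` or `"som"`.
#' @param group_value Value of the held-fixed variable (a SOM level when the
#'   perturbation is moisture, and vice versa).
#' @param ... Passed to [detect_auto_peaks()].
#' @return Data frame of planted peaks (`wavelength`, `strength`,
#'   `prominence`).
#' @export
expected_auto_peaks <- function(cfg, perturbation_name, group_value, ...) {
  cfg0 <- cfg
  cfg0$noise_sd <- 0
  cfg0$noise_sd_blue <- 0
  levels <- if (perturbation_name == "moisture") cfg$moisture_levels else cfg$som_levels
  rows <- t(vapply(levels, function(p) {
    if (perturbation_name == "moisture") {
      noiseless_spectrum(cfg0, som = group_value, moisture = p)
    } else {
      noiseless_spectrum(cfg0, som = p, moisture = group_value)
    }
  }, numeric(length(cfg$grid))))
  s <- spectrum_set(cfg$grid, rows,
                    som_pct = if (perturbation_name == "som") levels else
                      rep(group_value, length(levels)),
                    moisture_pct = if (perturbation_name == "moisture") levels else
                      rep(group_value, length(levels)))
  detect_auto_peaks(synchronous_map(dynamic_spectra(s, perturbation_name)), ...)
}

#' Deterministic 50-sample SOM level sequence
#'
#' Quantiles of a lognormal distribution matched by moments to the reference
#' field population (mean 2.22% w/w, sd 1.25% w/w), clipped to the observed
#' range 0.40-7.92% w/w. Used as the SOM levels of the default regression
#' study.
#'
#' @param n Number of levels.
#' @param mean,sd Target mean and sd, % w/w.
#' @param min,max Clipping range, % w/w.
#' @return Sorted numeric vector of length `n`.
#' @export
som_study_levels <- function(n = 50, mean = 2.22, sd = 1.25,
                             min = 0.40, max = 7.92) {
  sdlog2 <- log(1 + (sd / mean)^2)
  meanlog <- log(mean) - sdlog2 / 2
  q <- stats::qlnorm(stats::ppoints(n), meanlog = meanlog, sdlog = sqrt(sdlog2))
  pmin(pmax(q, min), max)
}
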