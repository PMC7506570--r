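#' Published reference values from the motivating loam-soil field study
#'
#' Small tables of printed results from the 50-sample moist loam-soil study
#' that motivates this package (the raw field spectra themselves were never
#' deposited). They serve as inputs for printed-value arithmetic — e.g.
#' percent changes of correlation strength or RPD between experiments — and
#' as qualitative targets for the synthetic-study properties.
#'
#' * `"autopeaks_moisture"` — auto-peak correlation strengths under moisture
#'   perturbation, one group per SOM category: columns `som_group_pct`,
#'   `peak`, `wavelength_nm`, `strength`.
#' * `"autopeaks_som"` — auto-peak strengths under SOM perturbation, one
#'   group per moisture level: columns `moisture_group_pct`, `peak`,
#'   `wavelength_nm`, `strength`.
#' * `"plsr_experiments"` — PLSR assessment statistics of the four
#'   band-selection experiments A-D: columns `experiment`, `n_bands`, `r2_c`,
#'   `rmsec`, `r2_cv`, `rmsecv`, `r2_p`, `rmsep`, `rpd`.
#'
#' @param which One of `"autopeaks_moisture"`, `"autopeaks_som"`,
#'   `"plsr_experiments"`.
#' @return A data frame.
#' @export
reference_table <- function(which = c("autopeaks_moisture", "autopeaks_som",
                                      "plsr_experiments")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0(which, ".csv"), package = "soilcos",
                      mustWork = TRUE)
  utils::read.csv(path)
}
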