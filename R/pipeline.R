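#' Assemble a pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis. Either `spectra_path`
#' (+ optional `metadata_path`) or `synthetic = TRUE` must be set.
#'
#' @param out_dir Output directory (created if absent).
#' @param spectra_path,metadata_path Input CSVs for field data, or `NULL`.
#' @param synthetic Use the synthetic generator instead of files.
#' @param synthetic_config A `synthetic_config`; defaults to
#'   [default_synthetic_config()] with the pipeline seed.
#' @param trim_lo,trim_hi Trim window in nm.
#' @param splice_junction Detector junction in nm, or `NULL` to skip splice
#'   correction (the synthetic generator has no junction artifact).
#' @param min_prominence_frac,min_separation Auto-peak detector parameters.
#' @param exclusion_half_width Half-width (nm) of the moisture exclusion
#'   windows in `band_mode = "detected"`.
#' @param band_mode `"preset"` uses [experiment_bandset()] verbatim;
#'   `"detected"` rebuilds the B/C exclusion windows from the detected
#'   moisture auto-peaks +/- `exclusion_half_width`.
#' @param experiments Subset of `c("A","B","C","D")` to run.
#' @param folds Outer/inner CV folds.
#' @param seed Integer seed for all stochastic stages.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, spectra_path = NULL, metadata_path = NULL,
                            synthetic = is.null(spectra_path),
                            synthetic_config = NULL,
                            trim_lo = 400, trim_hi = 2450,
                            splice_junction = NULL,
                            min_prominence_frac = 0.05, min_separation = 20,
                            exclusion_half_width = 51,
                            band_mode = c("preset", "detected"),
                            experiments = c("A", "B", "C", "D"),
                            folds = 5, seed = 1L) {
  band_mode <- match.arg(band_mode)
  if (!synthetic && is.null(spectra_path)) {
    stop("either spectra_path or synthetic = TRUE is required")
  }
  if (synthetic && is.null(synthetic_config)) {
    synthetic_config <- default_synthetic_config(seed = seed)
  }
  structure(list(out_dir = out_dir, spectra_path = spectra_path,
                 metadata_path = metadata_path, synthetic = synthetic,
                 synthetic_config = synthetic_config, trim_lo = trim_lo,
                 trim_hi = trim_hi, splice_junction = splice_junction,
                 min_prominence_frac = min_prominence_frac,
                 min_separation = min_separation,
                 exclusion_half_width = exclusion_half_width,
                 band_mode = band_mode, experiments = experiments,
                 folds = folds, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror [pipeline_config()] arguments; a nested
#' `synthetic_config` block is passed to [read_synthetic_config()] semantics
#' (peaks as named argument maps).
#'
#' @param path YAML file path.
#' @param out_dir Optional override of the configured output directory.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synthetic_config)) {
    sc <- y$synthetic_config
    peaks <- lapply(sc$peaks, function(p) do.call(peak_spec, p))
    grid <- if (is.null(sc$grid)) default_grid() else
      seq(sc$grid$lo, sc$grid$hi, by = if (is.null(sc$grid$by)) 1 else sc$grid$by)
    y$synthetic_config <- do.call(synthetic_config,
      c(list(grid = grid, peaks = peaks),
        sc[setdiff(names(sc), c("peaks", "grid"))]))
  }
  if (!is.null(out_dir)) y$out_dir <- out_dir
  do.call(pipeline_config, y)
}

# Log a pipeline message to stderr and the run log.
pipeline_log <- function(con, ...) {
  msg <- paste0(...)
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the full 2D-COS band-selection analysis
#'
#' Stages, in order: load or simulate spectra; trim to the working window;
#' optional splice correction; synchronous 2D-COS auto-peak tables for the
#' moisture perturbation (grouped by SOM) and the SOM perturbation (grouped
#' by moisture); moisture exclusion windows; band sets for the requested
#' experiments; one nested-CV PLSR run per experiment; summary report. Every
#' artifact is written under `cfg$out_dir` and stamped with the config hash
#' and seed. A stage failure aborts with the stage name; artifacts written by
#' earlier stages are retained.
#'
#' @param cfg A [pipeline_config].
#' @return Invisibly, a list with the in-memory artifacts: `study`,
#'   `peaks_moisture`, `peaks_som`, `bandsets`, `metrics` (data frame),
#'   `config_hash`, `files`.
#' @export
run_pipeline <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con))
  files <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # config stamp: hash covers every analysis parameter but not the output
  # location, so reruns of one analysis share a hash
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  cfg_path <- file.path(cfg$out_dir, "config.yaml")
  yaml::write_yaml(strip(cfg[setdiff(names(cfg), "out_dir")]), cfg_path)
  config_hash <- unname(tools::md5sum(cfg_path))
  stamp <- c(config_hash = config_hash, seed = cfg$seed)
  pipeline_log(log_con, "config hash ", config_hash, ", seed ", cfg$seed)

  study <- stage("load", {
    if (cfg$synthetic) {
      pipeline_log(log_con, "simulating study: ",
                   length(cfg$synthetic_config$som_levels), " SOM x ",
                   length(cfg$synthetic_config$moisture_levels),
                   " moisture levels")
      generate_study(cfg$synthetic_config)
    } else {
      pipeline_log(log_con, "reading spectra from ", cfg$spectra_path)
      read_spectra_table(cfg$spectra_path, cfg$metadata_path)
    }
  })
  study <- stage("trim", trim_wavelengths(study, cfg$trim_lo, cfg$trim_hi))
  if (!is.null(cfg$splice_junction)) {
    study <- stage("splice", splice_correct(study, cfg$splice_junction))
    pipeline_log(log_con, "splice-corrected at ", cfg$splice_junction, " nm")
  }
  f <- file.path(cfg$out_dir, "spectra_preprocessed.csv")
  write_spectra_table(study, f,
                      metadata_path = file.path(cfg$out_dir, "metadata.csv"))
  files <- c(files, f)

  has_moisture <- !is.null(study$moisture_pct)
  has_som <- !is.null(study$som_pct)

  peaks_moisture <- peaks_som <- NULL
  if (has_moisture && has_som) {
    peaks_moisture <- stage("cos2d_moisture", correlation_strength_table(
      study, "moisture", group_by = "som",
      min_prominence_frac = cfg$min_prominence_frac,
      min_separation = cfg$min_separation))
    f <- file.path(cfg$out_dir, "autopeaks_moisture_perturbation.csv")
    utils::write.csv(peaks_moisture, f, row.names = FALSE)
    files <- c(files, f)
    peaks_som <- stage("cos2d_som", correlation_strength_table(
      study, "som", group_by = "moisture",
      min_prominence_frac = cfg$min_prominence_frac,
      min_separation = cfg$min_separation))
    f <- file.path(cfg$out_dir, "autopeaks_som_perturbation.csv")
    utils::write.csv(peaks_som, f, row.names = FALSE)
    files <- c(files, f)
    pipeline_log(log_con, "2D-COS: ", nrow(peaks_moisture),
                 " moisture-perturbation and ", nrow(peaks_som),
                 " SOM-perturbation auto-peak rows (prominence >= ",
                 cfg$min_prominence_frac, " of max, separation >= ",
                 cfg$min_separation, " nm, normalization 1/(m-1))")
  } else {
    pipeline_log(log_con, "2D-COS stages skipped: need both som_pct and moisture_pct")
  }

  bandsets <- stage("bands", {
    bs <- lapply(cfg$experiments, experiment_bandset)
    names(bs) <- cfg$experiments
    if (cfg$band_mode == "detected" && !is.null(peaks_moisture)) {
      # rebuild the B/C exclusion windows from detected moisture auto-peaks
      pk <- stats::aggregate(strength ~ wavelength_nm, peaks_moisture, max)
      pk <- pk[order(-pk$strength), ][seq_len(min(3, nrow(pk))), ]
      excl <- band_set(pk$wavelength_nm - cfg$exclusion_half_width,
                       pk$wavelength_nm + cfg$exclusion_half_width)
      ex_f <- file.path(cfg$out_dir, "moisture_exclusion_windows.json")
      bandset_to_json(excl, ex_f)
      files <- c(files, ex_f)
      pipeline_log(log_con, "detected exclusion windows: ",
                   paste(sprintf("%g-%g", excl$lo, excl$hi), collapse = ", "))
      if ("B" %in% names(bs)) bs$B <- exclude_windows(c(cfg$trim_lo, cfg$trim_hi),
                                                      excl, label = "B")
      if ("C" %in% names(bs)) bs$C <- exclude_windows(c(500, cfg$trim_hi),
                                                      excl, label = "C")
    }
    bs
  })
  for (tag in names(bandsets)) {
    f <- file.path(cfg$out_dir, paste0("bandset_", tag, ".json"))
    bandset_to_json(bandsets[[tag]], f)
    files <- c(files, f)
  }

  metrics <- NULL
  if (has_som) {
    metrics <- stage("plsr", {
      rows <- lapply(names(bandsets), function(tag) {
        m <- run_experiment(study, bandsets[[tag]], folds = cfg$folds,
                            seed = cfg$seed)
        pipeline_log(log_con, "experiment ", tag, ": f per fold = ",
                     paste(m$f_per_fold, collapse = ","),
                     sprintf(", RMSEP = %.4f, RPD = %.3f (%s)",
                             m$rmsep, m$rpd, m$rpd_class))
        as.data.frame(m)
      })
      do.call(rbind, rows)
    })
    metrics <- cbind(metrics, config_hash = config_hash, seed = cfg$seed)
    f <- file.path(cfg$out_dir, "experiment_metrics.csv")
    utils::write.csv(metrics, f, row.names = FALSE)
    files <- c(files, f)
  } else {
    pipeline_log(log_con, "PLSR stage refused: metadata error, som_pct absent")
  }

  artifacts <- list(study = study, peaks_moisture = peaks_moisture,
                    peaks_som = peaks_som, bandsets = bandsets,
                    metrics = metrics, config_hash = config_hash,
                    seed = cfg$seed, files = files, out_dir = cfg$out_dir)
  report <- make_report(artifacts)
  writeLines(report, file.path(cfg$out_dir, "summary.txt"))
  invisible(artifacts)
}

#' Render a human-readable summary of pipeline artifacts
#'
#' Produces the auto-peak tables, the experiment metrics table and
#' percent-change statements (e.g. the RPD improvement of the
#' moisture-excluded band set over the SOM-bands-only set). Missing
#' artifacts are listed as absent; the report still renders.
#'
#' @param artifacts The list returned by [run_pipeline()].
#' @return Character vector of report lines.
#' @export
make_report <- function(artifacts) {
  out <- c("Synchronous 2D-COS band-selection analysis",
           paste0("config hash: ", artifacts$config_hash,
                  "   seed: ", artifacts$seed), "")
  fmt_peaks <- function(tab, head) {
    if (is.null(tab)) return(c(head, "  [absent]", ""))
    if (!nrow(tab)) return(c(head, "  no peaks detected", ""))
    c(head, sprintf("  group %-8s %7.0f nm   strength %.6f",
                    tab$group_label, tab$wavelength_nm, tab$strength), "")
  }
  out <- c(out,
           fmt_peaks(artifacts$peaks_moisture,
                     "Auto-peaks, moisture perturbation (grouped by SOM %):"),
           fmt_peaks(artifacts$peaks_som,
                     "Auto-peaks, SOM perturbation (grouped by moisture %):"))
  m <- artifacts$metrics
  if (is.null(m)) {
    out <- c(out, "PLSR experiments: [absent]", "")
  } else {
    out <- c(out, "PLSR experiments:",
             sprintf("  %-2s bands=%-5d f=%-3d R2c=%.3f RMSEC=%.3f R2cv=%.3f RMSECV=%.3f R2p=%.3f RMSEP=%.3f RPD=%.2f %s",
                     m$label, m$n_bands, m$n_components, m$r2_c, m$rmsec,
                     m$r2_cv, m$rmsecv, m$r2_p, m$rmsep, m$rpd, m$rpd_class),
             "")
    if (all(c("B", "D") %in% m$label)) {
      imp <- percent_change(m$rpd[m$label == "D"], m$rpd[m$label == "B"])
      out <- c(out, sprintf(
        "RPD change, SOM-bands-only (D) -> moisture-excluded (B): %+.0f%%", imp))
    }
    if (all(c("C", "D") %in% m$label)) {
      imp <- percent_change(m$rpd[m$label == "D"], m$rpd[m$label == "C"])
      out <- c(out, sprintf(
        "RPD change, SOM-bands-only (D) -> moisture+noise-excluded (C): %+.0f%%", imp))
    }
  }
  out
}
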