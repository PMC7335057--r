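# File formats and pipeline orchestration. Interchange formats are plain
# CSV (traces: time_s,diameter_mm,quality_pct,blink with empty fields for
# missing diameters; spectra: wavelength_nm,radiance_W_m2_sr_nm) and a YAML
# design config tying stimuli, anchors, exposure times and models together.

TRACE_COLS <- c("time_s", "diameter_mm", "quality_pct", "blink")

#' Write / read a pupil trace CSV
#'
#' Lossless round-trip of a [pupil_trace()] through the four-column CSV
#' `time_s,diameter_mm,quality_pct,blink`; missing diameters are written as
#' empty fields.
#'
#' @param trace A [pupil_trace()].
#' @param path File path.
#' @param fs Sampling rate assumed when reading.
#' @param meta Metadata attached to the trace on reading.
#' @return `read_trace` returns a [pupil_trace()]; `write_trace` returns
#'   `path` invisibly.
#' @export
write_trace <- function(trace, path) {
  data.table::fwrite(as.data.frame(trace), path, na = "")
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path, fs = 120, meta = list()) {
  dt <- data.table::fread(path, sep = ",", header = TRUE,
                          na.strings = "")
  if (!all(TRACE_COLS %in% names(dt)))
    stop(sprintf("trace file %s: missing column(s) %s", path,
                 paste(setdiff(TRACE_COLS, names(dt)), collapse = ", ")),
         call. = FALSE)
  if (any(diff(dt$time_s) <= 0)) {
    bad <- which(diff(dt$time_s) <= 0)[1] + 1L
    stop(sprintf("trace file %s: non-monotone time at line %d", path,
                 bad + 1L), call. = FALSE)
  }
  pupil_trace(dt$time_s, dt$diameter_mm, dt$quality_pct,
              as.logical(dt$blink), fs = fs, meta = meta)
}

#' Write / read a spectrum CSV
#'
#' Two-column CSV `wavelength_nm,radiance_W_m2_sr_nm` with header. Reading
#' validates and resamples onto the package's 1 nm grid.
#'
#' @param spec A [light_spectrum()].
#' @param path File path.
#' @return `read_spectrum` returns a [light_spectrum()]; `write_spectrum`
#'   returns `path` invisibly.
#' @export
write_spectrum <- function(spec, path) {
  data.table::fwrite(data.frame(wavelength_nm = spec$wavelength_nm,
                                radiance_W_m2_sr_nm = spec$radiance), path)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  dt <- data.table::fread(path, sep = ",", header = TRUE)
  need <- c("wavelength_nm", "radiance_W_m2_sr_nm")
  if (!all(need %in% names(dt)))
    stop(sprintf("spectrum file %s: expected columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  if (nrow(dt) < 2)
    stop(sprintf("spectrum file %s: need at least two rows", path),
         call. = FALSE)
  if (any(diff(dt$wavelength_nm) <= 0)) {
    bad <- which(diff(dt$wavelength_nm) <= 0)[1] + 1L
    stop(sprintf("spectrum file %s: unsorted wavelengths at line %d", path,
                 bad + 1L), call. = FALSE)
  }
  if (any(dt$radiance_W_m2_sr_nm < 0))
    stop(sprintf("spectrum file %s: negative radiance", path), call. = FALSE)
  light_spectrum(dt$wavelength_nm, dt$radiance_W_m2_sr_nm)
}

#' Write a synthetic cohort to disk
#'
#' Writes every recording of a [generate_cohort()] result as a trace CSV
#' (named `<subject>_<stimulus>_<role>.csv`) plus a `manifest.json`
#' recording subjects, stimuli, seeds and the per-recording ground-truth
#' steady-state diameters.
#'
#' @param cohort A `"synthetic_cohort"`.
#' @param dir Output directory (created if needed).
#' @return The manifest (invisibly).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  recs <- lapply(cohort$recordings, function(r) {
    fn <- sprintf("%s_%s_%s.csv", r$subject, r$stimulus, r$role)
    write_trace(r$raw, file.path(dir, fn))
    list(subject = r$subject, stimulus = r$stimulus, role = r$role,
         file = fn, steady_state_mm = r$truth$steady_state_mm)
  })
  manifest <- list(n = cohort$n, seed = cohort$seed, fs = cohort$fs,
                   duration_s = cohort$duration_s,
                   stimuli = cohort$stimuli, recordings = recs)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a benchmark design config
#'
#' YAML with keys: `stimuli` (list of `label` plus either `spectrum`
#' (CSV path) or `luminance`, optionally `melanopic`), `anchor` (label of
#' the anchor condition or `none`), `exposure_times_s`, `models`,
#' `field` (`diameter_deg`, `conversion`), `age_years`, `eyes`, and
#' optional `preprocess` overrides for [preprocess_params()].
#'
#' @param path YAML file path.
#' @return The validated config list.
#' @export
read_design <- function(path) {
  cfg <- yaml::read_yaml(path)
  labs <- vapply(cfg$stimuli, `[[`, "", "label")
  if (anyDuplicated(labs))
    stop("stimulus labels must be unique", call. = FALSE)
  cfg
}

#' Run the full synthetic benchmark pipeline
#'
#' Orchestrates the published analysis on a directory of trace CSVs (as
#' written by [write_cohort()]): cleans every recording, extracts absolute
#' diameters at the exposure times for the model-error comparison,
#' baseline-corrects each stimulus trace against its anchor for the
#' repeated-measures ANOVA, and summarizes predicted-minus-measured errors
#' per model, stimulus and exposure time.
#'
#' @param traces_dir Directory containing the trace CSVs and
#'   `manifest.json`.
#' @param models Character vector of model ids (see [pupil_model_ids()]).
#' @param luminance_cdm2 Stimulus luminance fed to the models.
#' @param age_years,eyes Observer parameters for the unified formula.
#' @param field [field_geometry()] of the adapting field.
#' @param exposure_times_s Extraction times in seconds.
#' @param params [preprocess_params()].
#' @param baseline_window_s Anchor baseline window, s.
#' @return List of class `"benchmark_report"`: `errors` (data.frame of
#'   [prediction_error()] rows), `anova` (one `"rm_anova"` per exposure
#'   time, on baseline-corrected diameters), `predictions`, `diameters`
#'   (long data.frame of extracted absolute and baseline-corrected
#'   diameters), and `params`.
#' @export
run_full_benchmark <- function(traces_dir,
                               models = c("crawford", "degroot_gebhard",
                                          "watson_yellott"),
                               luminance_cdm2 = 100,
                               age_years = 22.2, eyes = 2,
                               field = benchmark_field(),
                               exposure_times_s = c(1, 60, 300),
                               params = preprocess_params(),
                               baseline_window_s = 10) {
  manifest <- jsonlite::read_json(file.path(traces_dir, "manifest.json"),
                                  simplifyVector = TRUE)
  recs <- manifest$recordings
  fs <- manifest$fs

  preds <- lapply(setNames(nm = models), function(m)
    predict_diameter(m, viewing_conditions(luminance_cdm2, field = field,
                                           age_years = age_years,
                                           eyes = eyes)))

  stim_rows <- recs[recs$role == "stimulus", ]
  rows <- list()
  for (i in seq_len(nrow(stim_rows))) {
    r <- stim_rows[i, ]
    stim <- clean_trace(read_trace(file.path(traces_dir, r$file), fs = fs),
                        params)$trace
    anchor_file <- recs$file[recs$role == "anchor" &
                             recs$subject == r$subject &
                             recs$stimulus == r$stimulus]
    if (length(anchor_file) != 1)
      stop(sprintf("stage baseline: no unique anchor for %s/%s",
                   r$subject, r$stimulus), call. = FALSE)
    anchor <- clean_trace(read_trace(file.path(traces_dir, anchor_file),
                                     fs = fs), params)$trace
    corr <- baseline_correct(stim, anchor, baseline_window_s)
    for (tx in exposure_times_s) {
      rows[[length(rows) + 1]] <- data.frame(
        subject = r$subject, stimulus = r$stimulus, exposure_time_s = tx,
        diameter_mm = extract_diameter(stim, tx),
        corrected_mm = extract_diameter(corr, tx))
    }
  }
  diam <- do.call(rbind, rows)

  errors <- do.call(rbind, lapply(models, function(m) {
    do.call(rbind, lapply(split(diam, list(diam$stimulus,
                                           diam$exposure_time_s)),
      function(g) prediction_error(preds[[m]], g$diameter_mm,
                                   stimulus = g$stimulus[1],
                                   exposure_time_s = g$exposure_time_s[1])))
  }))
  rownames(errors) <- NULL

  anova <- lapply(setNames(nm = as.character(exposure_times_s)),
    function(tx) {
      g <- diam[diam$exposure_time_s == as.numeric(tx), ]
      wide <- tapply(g$corrected_mm, list(g$subject, g$stimulus), mean)
      if (nrow(wide) >= 3 && ncol(wide) >= 2 && !anyNA(wide))
        rm_anova(wide) else NULL
    })

  structure(list(errors = errors, anova = anova, predictions = preds,
                 diameters = diam,
                 params = list(models = models,
                               luminance_cdm2 = luminance_cdm2,
                               age_years = age_years, eyes = eyes,
                               exposure_times_s = exposure_times_s,
                               baseline_window_s = baseline_window_s)),
            class = "benchmark_report")
}

#' Write a benchmark report to disk
#'
#' Writes `errors.csv`, `diameters.csv` and `report.json` (error table,
#' ANOVA summaries, model predictions and run parameters).
#'
#' @param report A `"benchmark_report"`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(report$errors, file.path(dir, "errors.csv"))
  data.table::fwrite(report$diameters, file.path(dir, "diameters.csv"))
  anova <- lapply(report$anova, function(a) if (is.null(a)) NULL else
    a[c("f_value", "df1", "df2", "p_value", "gg_applied", "gg_epsilon",
        "mauchly_w", "mauchly_chi2", "mauchly_df", "mauchly_p", "eta_sq")])
  preds <- lapply(report$predictions, function(p)
    list(model = p$model_id, diameter_mm = p$diameter_mm))
  jsonlite::write_json(list(predictions = preds, anova = anova,
                            params = report$params),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("benchmark_report\n")
  cat("model predictions:\n")
  for (p in x$predictions)
    cat(sprintf("  %-16s %.3f mm\n", p$model_id, p$diameter_mm))
  cat("mean prediction error (predicted - measured), mm:\n")
  print(x$errors, row.names = FALSE, digits = 3)
  invisible(x)
}
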