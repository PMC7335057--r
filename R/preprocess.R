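# Pupil-trace cleaning: blink removal, ellipse-fit quality filtering,
# velocity-percentile outlier rejection, linear interpolation and
# Savitzky-Golay smoothing with an unsmoothed lead-in. No stage ever alters
# the time axis; artifact samples are marked missing (NA) in place.

#' Pupil diameter time series
#'
#' A uniformly sampled pupil trace with per-sample ellipse-fit quality and
#' blink flags, the substrate of the preprocessing pipeline.
#'
#' @param time_s Strictly increasing, uniformly sampled times (s). The step
#'   must equal `1/fs` within 1 microsecond.
#' @param diameter_mm Pupil diameter in mm; `NA` marks missing samples.
#'   Present values must lie in (0.5, 10) mm.
#' @param quality_pct Per-sample ellipse-fitting accuracy in percent.
#' @param blink Logical blink flags.
#' @param fs Sampling rate in Hz (default 120, the recorder's frame rate).
#' @param meta Optional list of metadata (subject id, stimulus label, eye).
#' @return Object of class `"pupil_trace"`.
#' @export
pupil_trace <- function(time_s, diameter_mm,
                        quality_pct = rep(100, length(time_s)),
                        blink = rep(FALSE, length(time_s)),
                        fs = 120, meta = list()) {
  n <- length(time_s)
  if (n < 2) stop("trace needs at least two samples", call. = FALSE)
  if (length(diameter_mm) != n || length(quality_pct) != n ||
      length(blink) != n)
    stop("trace fields must have equal length", call. = FALSE)
  dt <- diff(time_s)
  if (any(dt <= 0)) stop("time must be strictly increasing", call. = FALSE)
  if (max(abs(dt - 1 / fs)) > 1e-6)
    stop("time axis not uniform at the stated sampling rate", call. = FALSE)
  present <- !is.na(diameter_mm)
  if (any(diameter_mm[present] <= 0.5 | diameter_mm[present] >= 10))
    stop("present diameters must lie in (0.5, 10) mm", call. = FALSE)
  if (any(quality_pct < 0 | quality_pct > 100, na.rm = TRUE))
    stop("quality must be a percentage in [0, 100]", call. = FALSE)
  structure(list(time_s = as.numeric(time_s),
                 diameter_mm = as.numeric(diameter_mm),
                 quality_pct = as.numeric(quality_pct),
                 blink = as.logical(blink),
                 fs = fs, meta = meta),
            class = "pupil_trace")
}

#' @export
print.pupil_trace <- function(x, ...) {
  n <- length(x$time_s)
  cat(sprintf("pupil_trace: %d samples @ %g Hz (%.1f s), %d missing\n",
              n, x$fs, x$time_s[n] - x$time_s[1], sum(is.na(x$diameter_mm))))
  invisible(x)
}

#' @export
as.data.frame.pupil_trace <- function(x, ...) {
  data.frame(time_s = x$time_s, diameter_mm = x$diameter_mm,
             quality_pct = x$quality_pct, blink = x$blink)
}

#' Preprocessing parameters
#'
#' Defaults mirror the published cleaning pipeline: ellipse-fit quality
#' threshold 97%, velocity percentile bounds 0.007% / 99.993%,
#' Savitzky-Golay window of 3001 samples (nearest odd count to 3000,
#' i.e. ~25 s at 120 Hz) with polynomial order 3, and an unsmoothed 3 s
#' lead-in that preserves the phasic constriction.
#'
#' @param min_quality_pct Samples with quality strictly below this are
#'   deleted (marked missing).
#' @param vel_lo_pctl,vel_hi_pctl Percentile bounds (in percent) on the
#'   per-recording velocity distribution.
#' @param sg_window_samples Odd Savitzky-Golay window length in samples.
#' @param sg_polyorder Polynomial order of the smoother.
#' @param unsmoothed_lead_s Seconds at the start left unsmoothed.
#' @param min_velocity_samples Below this number of present samples the
#'   velocity percentiles are considered meaningless and the stage passes
#'   the trace through with a warning.
#' @return List of class `"preprocess_params"`.
#' @export
preprocess_params <- function(min_quality_pct = 97,
                              vel_lo_pctl = 0.007, vel_hi_pctl = 99.993,
                              sg_window_samples = 3001, sg_polyorder = 3,
                              unsmoothed_lead_s = 3,
                              min_velocity_samples = 1000) {
  if (!(vel_lo_pctl > 0 && vel_lo_pctl < vel_hi_pctl && vel_hi_pctl < 100))
    stop("velocity percentiles must satisfy 0 < lo < hi < 100", call. = FALSE)
  if (sg_window_samples %% 2 != 1 ||
      sg_window_samples < sg_polyorder + 2)
    stop("Savitzky-Golay window must be odd and >= polyorder + 2",
         call. = FALSE)
  structure(list(min_quality_pct = min_quality_pct,
                 vel_lo_pctl = vel_lo_pctl, vel_hi_pctl = vel_hi_pctl,
                 sg_window_samples = sg_window_samples,
                 sg_polyorder = sg_polyorder,
                 unsmoothed_lead_s = unsmoothed_lead_s,
                 min_velocity_samples = min_velocity_samples),
            class = "preprocess_params")
}

#' Delete low-quality samples
#'
#' Marks samples whose ellipse-fitting accuracy is strictly below the
#' threshold as missing; the time axis is unchanged.
#'
#' @param trace A [pupil_trace()].
#' @param params A [preprocess_params()].
#' @return The trace with low-quality samples set to `NA`.
#' @export
quality_filter <- function(trace, params = preprocess_params()) {
  trace$diameter_mm[trace$quality_pct < params$min_quality_pct] <- NA_real_
  if (all(is.na(trace$diameter_mm)))
    stop("quality filter removed every sample", call. = FALSE)
  trace
}

#' Delete blink-flagged samples
#'
#' Marks every blink-flagged sample missing. No temporal padding is applied
#' around blinks; widen the flags upstream if padding is wanted.
#'
#' @param trace A [pupil_trace()].
#' @return The trace with blink samples set to `NA`.
#' @export
blink_filter <- function(trace) {
  trace$diameter_mm[trace$blink] <- NA_real_
  trace
}

#' Remove velocity outliers
#'
#' Numerically differentiates the diameter over consecutive present samples
#' and marks the later sample of any pair whose velocity falls strictly
#' outside the recording's own percentile bounds (defaults 0.007% and
#' 99.993%). With fewer present samples than `min_velocity_samples` the
#' percentiles are meaningless; the trace passes through with a warning.
#'
#' @param trace A [pupil_trace()].
#' @param params A [preprocess_params()].
#' @return The trace with outlier samples set to `NA`.
#' @export
velocity_filter <- function(trace, params = preprocess_params()) {
  idx <- which(!is.na(trace$diameter_mm))
  if (length(idx) < params$min_velocity_samples) {
    warning("too few present samples for velocity percentiles; pass-through",
            call. = FALSE)
    return(trace)
  }
  v <- diff(trace$diameter_mm[idx]) / diff(trace$time_s[idx])
  bounds <- quantile(v, c(params$vel_lo_pctl, params$vel_hi_pctl) / 100,
                     names = FALSE)
  bad <- v < bounds[1] | v > bounds[2]
  trace$diameter_mm[idx[-1][bad]] <- NA_real_
  trace
}

#' Linearly interpolate missing samples
#'
#' Interior gaps are filled linearly between the bounding present samples;
#' leading and trailing gaps take the nearest present value (linear
#' extrapolation could produce non-physical diameters).
#'
#' @param trace A [pupil_trace()].
#' @return A gap-free trace.
#' @export
interpolate_gaps <- function(trace) {
  present <- !is.na(trace$diameter_mm)
  if (sum(present) < 2)
    stop("need at least two present samples to interpolate", call. = FALSE)
  if (all(present)) return(trace)
  trace$diameter_mm <- approx(trace$time_s[present],
                              trace$diameter_mm[present],
                              xout = trace$time_s, rule = 2)$y
  trace
}

# Savitzky-Golay filtering: interior samples through the centered
# least-squares FIR kernel (stats::filter), edge samples by refitting the
# polynomial on the truncated window. Designs use scaled abscissae so the
# order-3 normal equations stay well conditioned at window 3001.
savgol_filter <- function(y, window, order) {
  n <- length(y)
  if (window > n) {
    window <- if (n %% 2 == 1) n else n - 1
    warning(sprintf("trace shorter than smoothing window; shrunk to %d",
                    window), call. = FALSE)
  }
  if (window < order + 2)
    stop("smoothing window shorter than polyorder + 2", call. = FALSE)
  hw <- (window - 1) %/% 2
  if (hw == 0) return(y)
  xr <- (-hw:hw) / hw
  A <- outer(xr, 0:order, `^`)
  h <- solve(crossprod(A), t(A))[1, ]          # center-evaluation kernel
  out <- as.numeric(stats::filter(y, rev(h), sides = 2))
  out[seq_len(hw)] <- savgol_edge(y, hw, order)
  out[n - seq_len(hw) + 1] <- savgol_edge(rev(y), hw, order)
  out
}

# Truncated-window refit for positions 1..hw: position i is fitted on
# samples 1..(i+hw) and evaluated in place. Prefix sums of the moments make
# the per-position normal equations O(1).
savgol_edge <- function(y, hw, order) {
  m <- 2 * hw                  # largest truncated window
  x <- (1:m) / hw
  S <- lapply(0:(2 * order), function(k) cumsum(x^k))
  Tm <- lapply(0:order, function(k) cumsum(x^k * y[1:m]))
  vapply(seq_len(hw), function(i) {
    w <- i + hw
    M <- matrix(0, order + 1, order + 1)
    for (k in 0:order) for (l in k:order)
      M[k + 1, l + 1] <- M[l + 1, k + 1] <- S[[k + l + 1]][w]
    b <- vapply(0:order, function(k) Tm[[k + 1]][w], numeric(1))
    beta <- solve(M, b)
    sum(beta * x[i]^(0:order))
  }, numeric(1))
}

#' Savitzky-Golay smoothing with an unsmoothed lead-in
#'
#' Local least-squares polynomial smoothing (default window 3001 samples,
#' order 3). Samples earlier than `unsmoothed_lead_s` seconds are returned
#' unmodified so the phasic constriction is not artificially flattened.
#' Edge samples are refitted on the truncated window. The trace must be
#' gap-free (run [interpolate_gaps()] first).
#'
#' @param trace A gap-free [pupil_trace()].
#' @param params A [preprocess_params()].
#' @return The smoothed trace.
#' @export
smooth_trace <- function(trace, params = preprocess_params()) {
  if (anyNA(trace$diameter_mm))
    stop("smoothing requires a gap-free trace", call. = FALSE)
  sm <- savgol_filter(trace$diameter_mm, params$sg_window_samples,
                      params$sg_polyorder)
  lead <- trace$time_s - trace$time_s[1] < params$unsmoothed_lead_s
  sm[lead] <- trace$diameter_mm[lead]
  trace$diameter_mm <- sm
  trace
}

#' Full trace-cleaning pipeline
#'
#' Applies, in order: blink removal, quality filtering, velocity-percentile
#' outlier rejection, linear interpolation, Savitzky-Golay smoothing with
#' an unsmoothed 3 s lead-in. Sample count and time axis are conserved
#' end-to-end.
#'
#' @param trace A raw [pupil_trace()].
#' @param params A [preprocess_params()].
#' @return List of class `"clean_trace"`: `trace` (the cleaned gap-free
#'   trace) and `log`, per-stage counts of newly missing samples
#'   (`missing_input`, `blink`, `quality`, `velocity`, `interpolated` — the
#'   total number of samples that were filled).
#' @export
clean_trace <- function(trace, params = preprocess_params()) {
  n_missing <- function(tr) sum(is.na(tr$diameter_mm))
  log <- list(missing_input = n_missing(trace))
  trace <- blink_filter(trace)
  log$blink <- n_missing(trace) - log$missing_input
  trace <- quality_filter(trace, params)
  log$quality <- n_missing(trace) - log$missing_input - log$blink
  trace <- velocity_filter(trace, params)
  log$velocity <- n_missing(trace) - log$missing_input - log$blink -
    log$quality
  log$interpolated <- n_missing(trace)
  trace <- interpolate_gaps(trace)
  trace <- smooth_trace(trace, params)
  structure(list(trace = trace, log = log), class = "clean_trace")
}

#' @export
print.clean_trace <- function(x, ...) {
  l <- x$log
  cat(sprintf(paste0("clean_trace: %d samples; removed %d blink, %d ",
                     "low-quality, %d velocity outliers (%d interpolated)\n"),
              length(x$trace$time_s), l$blink, l$quality, l$velocity,
              l$interpolated))
  invisible(x)
}
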