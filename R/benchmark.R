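# Comparing model predictions against measured traces: subtractive baseline
# correction, windowed diameter extraction at fixed exposure times,
# prediction-error summaries, offset correction, and a one-way
# within-subject ANOVA with Mauchly's sphericity test, Greenhouse-Geisser
# correction and Bonferroni pairwise t-tests.

#' Subtractive baseline correction
#'
#' Subtracts from a stimulus trace the subject's baseline diameter, taken
#' as the mean diameter over the final `window_s` seconds of the preceding
#' anchor (re-adaptation) trace.
#'
#' @param stim_trace Stimulus [pupil_trace()] (clean, gap-free).
#' @param anchor_trace Anchor [pupil_trace()] recorded immediately before.
#' @param window_s Baseline window in seconds (default 10, the convention
#'   of taking the mean of the last ten seconds of adaptation).
#' @return The stimulus trace with `diameter_mm` replaced by the corrected
#'   (stimulus minus baseline) values; the baseline is stored in
#'   `meta$baseline_mm`.
#' @export
baseline_correct <- function(stim_trace, anchor_trace, window_s = 10) {
  t_end <- tail(anchor_trace$time_s, 1)
  if (t_end - anchor_trace$time_s[1] < window_s)
    stop("anchor trace shorter than the baseline window", call. = FALSE)
  sel <- anchor_trace$time_s >= t_end - window_s
  baseline <- mean(anchor_trace$diameter_mm[sel], na.rm = TRUE)
  if (!is.finite(baseline))
    stop("no present anchor samples in the baseline window", call. = FALSE)
  stim_trace$diameter_mm <- stim_trace$diameter_mm - baseline
  stim_trace$meta$baseline_mm <- baseline
  class(stim_trace) <- c("baseline_corrected", class(stim_trace))
  stim_trace
}

#' Extract the diameter at an exposure time
#'
#' Mean diameter over a window around exposure time `t_s` (seconds from
#' trace start). The window is centered, `[t - w/2, t + w/2]`, but slides
#' to stay inside the trace: at `t_s` equal to the trace end the window is
#' right-aligned (e.g. `[299, 300]` for extraction at 300 s from a 300 s
#' trace).
#'
#' @param trace A gap-free [pupil_trace()].
#' @param t_s Exposure time in seconds, relative to trace start.
#' @param window_s Averaging window length in seconds (default 1).
#' @return Mean diameter in mm.
#' @export
extract_diameter <- function(trace, t_s, window_s = 1) {
  t0 <- trace$time_s[1]
  dur <- tail(trace$time_s, 1) - t0
  if (t_s < 0 || t_s > dur || window_s > dur)
    stop("extraction window outside the trace", call. = FALSE)
  lo <- t_s - window_s / 2
  if (lo < 0) lo <- 0
  if (lo + window_s > dur) lo <- dur - window_s
  sel <- trace$time_s - t0 >= lo & trace$time_s - t0 <= lo + window_s
  mean(trace$diameter_mm[sel], na.rm = TRUE)
}

#' Prediction-error summary
#'
#' Mean and sample standard deviation (n - 1 denominator) of
#' (predicted - measured) over a set of measured diameters.
#'
#' @param prediction A `"model_prediction"` from [predict_diameter()], or a
#'   bare predicted diameter in mm.
#' @param measured_mm Numeric vector of measured diameters (mm), one per
#'   subject or repetition.
#' @param stimulus,exposure_time_s Optional labels carried into the result.
#' @return A one-row data.frame: `model_id`, `stimulus`, `exposure_time_s`,
#'   `mean_error_mm`, `sd_error_mm`, `n`.
#' @export
prediction_error <- function(prediction, measured_mm, stimulus = NA,
                             exposure_time_s = NA) {
  if (inherits(prediction, "model_prediction")) {
    model_id <- prediction$model_id
    pred <- prediction$diameter_mm
  } else {
    model_id <- NA_character_
    pred <- as.numeric(prediction)
  }
  measured_mm <- measured_mm[!is.na(measured_mm)]
  n <- length(measured_mm)
  if (n < 1) stop("empty measurement set", call. = FALSE)
  err <- pred - measured_mm
  data.frame(model_id = model_id, stimulus = stimulus,
             exposure_time_s = exposure_time_s,
             mean_error_mm = mean(err),
             sd_error_mm = if (n > 1) sd(err) else 0,
             n = n)
}

#' Offset correction of condition-mean errors
#'
#' Centers a set of per-condition mean prediction errors on their
#' unweighted mean: the offset is subtracted from each condition mean, so
#' the corrected errors sum to zero. This is the simple correction that
#' makes a luminance-only model usable at short exposure times, where the
#' error is nearly constant across spectra.
#'
#' @param mean_errors_mm Named or unnamed numeric vector of condition-mean
#'   errors (mm), length >= 2.
#' @return List with `offset_mm` and `corrected_mm`.
#' @export
offset_correct <- function(mean_errors_mm) {
  if (length(mean_errors_mm) < 2)
    stop("offset correction needs at least two condition means", call. = FALSE)
  offset <- mean(mean_errors_mm)
  list(offset_mm = offset, corrected_mm = mean_errors_mm - offset)
}

#' One-way within-subject (repeated-measures) ANOVA
#'
#' Omnibus test of a condition effect on a complete subjects x conditions
#' matrix, with Mauchly's sphericity test (chi-square approximation),
#' Greenhouse-Geisser epsilon applied to both degrees of freedom when
#' Mauchly's p < 0.05, eta-squared effect sizes, and Bonferroni-corrected
#' pairwise paired t-tests.
#'
#' Sums of squares follow the definitional decomposition
#' SS_total = SS_subject + SS_condition + SS_error. Mauchly's W and the
#' Greenhouse-Geisser epsilon are computed from the sample covariance of
#' the data projected onto an orthonormal contrast basis. The reported
#' `eta_sq` is the classical SS_condition / SS_total, which for this design
#' coincides with the generalized eta-squared (`eta_sq_generalized`);
#' `eta_sq_partial` is also returned.
#'
#' @param data Numeric matrix or data.frame, rows = subjects (n >= 3),
#'   columns = conditions (k >= 2), no missing cells.
#' @param gg_threshold Mauchly p-value below which the Greenhouse-Geisser
#'   correction is applied (default 0.05).
#' @return Object of class `"rm_anova"`: a list with `f_value`, `df1`,
#'   `df2`, `p_value`, `gg_applied`, `gg_epsilon`, `mauchly_w`,
#'   `mauchly_chi2`, `mauchly_df`, `mauchly_p`, `eta_sq`,
#'   `eta_sq_generalized`, `eta_sq_partial`, and `pairwise` (data.frame:
#'   `pair`, `mean_diff_mm`, `t`, `df`, `p`, `p_bonferroni`).
#' @export
rm_anova <- function(data, gg_threshold = 0.05) {
  y <- as.matrix(data)
  if (anyNA(y)) stop("missing cells are not allowed (no imputation)",
                     call. = FALSE)
  n <- nrow(y); k <- ncol(y)
  if (n < 3 || k < 2)
    stop("need at least 3 subjects and 2 conditions", call. = FALSE)
  if (is.null(colnames(y))) colnames(y) <- paste0("c", seq_len(k))

  grand <- mean(y)
  ss_subj <- k * sum((rowMeans(y) - grand)^2)
  ss_cond <- n * sum((colMeans(y) - grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_cond
  df1 <- k - 1
  df2 <- (n - 1) * (k - 1)
  ms_cond <- ss_cond / df1
  ms_err <- ss_err / df2
  f_value <- ms_cond / ms_err

  # sphericity: covariance of the orthonormal-contrast projection
  C <- contr_orthonormal(k)
  S <- crossprod(C, stats::cov(y)) %*% C
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  w <- if (all(ev > 0)) prod(ev) / (mean(ev))^df1 else 0
  dfm <- k * df1 / 2 - 1
  if (df1 > 1) {
    dd <- 1 - (2 * df1^2 + df1 + 2) / (6 * df1 * (n - 1))
    chi2 <- -(n - 1) * dd * log(max(w, .Machine$double.xmin))
    mauchly_p <- stats::pchisq(chi2, dfm, lower.tail = FALSE)
  } else {
    # k = 2: sphericity holds trivially
    w <- 1; chi2 <- 0; dfm <- 0; mauchly_p <- 1
  }
  eps <- sum(ev)^2 / (df1 * sum(ev^2))
  eps <- min(max(eps, 1 / df1), 1)

  gg_applied <- df1 > 1 && mauchly_p < gg_threshold
  df1_used <- if (gg_applied) eps * df1 else df1
  df2_used <- if (gg_applied) eps * df2 else df2
  p_value <- pf(f_value, df1_used, df2_used, lower.tail = FALSE)

  # pairwise paired t-tests, Bonferroni multiplication
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  pw <- do.call(rbind, lapply(seq_len(m), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    tt <- t.test(y[, i1], y[, i2], paired = TRUE)
    data.frame(pair = paste(colnames(y)[i1], colnames(y)[i2], sep = " vs "),
               mean_diff_mm = unname(tt$estimate),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value,
               p_bonferroni = min(1, tt$p.value * m))
  }))

  structure(list(
    f_value = f_value, df1 = df1_used, df2 = df2_used, p_value = p_value,
    gg_applied = gg_applied, gg_epsilon = eps,
    mauchly_w = w, mauchly_chi2 = chi2, mauchly_df = dfm,
    mauchly_p = mauchly_p,
    eta_sq = ss_cond / ss_tot,
    eta_sq_generalized = ss_cond / (ss_cond + ss_subj + ss_err),
    eta_sq_partial = ss_cond / (ss_cond + ss_err),
    ss = c(subject = ss_subj, condition = ss_cond, error = ss_err,
           total = ss_tot),
    n = n, k = k, pairwise = pw), class = "rm_anova")
}

# orthonormal basis of the contrast space (k x (k-1)), columns orthonormal
# and orthogonal to the unit vector
contr_orthonormal <- function(k) {
  H <- diag(k) - matrix(1 / k, k, k)
  qr.Q(qr(H))[, seq_len(k - 1), drop = FALSE]
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Mauchly's W = %.4f, chi2(%g) = %.3f, p = %.3g%s\n",
              x$mauchly_w, x$mauchly_df, x$mauchly_chi2, x$mauchly_p,
              if (x$gg_applied) " -> Greenhouse-Geisser applied" else ""))
  cat(sprintf("F(%.3g, %.3g) = %.3f, p = %.3g, eta^2 = %.3f (GG eps = %.3f)\n",
              x$df1, x$df2, x$f_value, x$p_value, x$eta_sq, x$gg_epsilon))
  cat("pairwise (Bonferroni):\n")
  print(x$pairwise, row.names = FALSE, digits = 4)
  invisible(x)
}
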