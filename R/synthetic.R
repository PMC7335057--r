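# Seeded synthetic study generator: LED channel spectra mixed to
# chromaticity/luminance targets, and raw pupil traces with phasic +
# melanopsin-scaled sustained constriction, blink dropouts, quality scores
# and inter/intrapersonal scatter. Every generator returns ground truth so
# the preprocessing and benchmarking stages can be validated end-to-end.

#' The 15 LED channels of the emulated luminaire
#'
#' Eleven narrow-band channels (Gaussian primaries at the published peak
#' wavelengths and FWHMs) and four phosphor-converted white channels
#' (two-Gaussian approximations labeled by their CCT).
#'
#' @return data.frame with columns `channel`, `kind`, `peak_nm`, `fwhm_nm`,
#'   `cct_label_K`.
#' @export
default_channels <- function() {
  peaks <- c(420, 450, 470, 505, 530, 545, 590, 610, 630, 660, 720)
  fwhms <- c(14, 18, 25, 29, 33, 105, 78, 17, 16, 17, 29)
  rbind(
    data.frame(channel = paste0("led", peaks), kind = "narrowband",
               peak_nm = peaks, fwhm_nm = fwhms, cct_label_K = NA_real_),
    data.frame(channel = paste0("white", c(2700, 4000, 5000, 5500)),
               kind = "phosphor_white", peak_nm = NA_real_,
               fwhm_nm = NA_real_, cct_label_K = c(2700, 4000, 5000, 5500)))
}

gaussian_sd <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

gaussian_line <- function(peak, fwhm, amplitude = 1) {
  amplitude * exp(-((WL_GRID - peak)^2) / (2 * gaussian_sd(fwhm)^2))
}

# Phosphor-white approximation: 450 nm pump + broad phosphor band. The
# pump/phosphor amplitude ratio is solved (uniroot on the CCT error) so the
# mixed chromaticity lands on the labeled CCT; cached per label.
white_channel_spd <- function(cct_label) {
  key <- paste0("white", cct_label)
  if (!is.null(.spectra_env$whites[[key]])) return(.spectra_env$whites[[key]])
  phos_peak <- stats::approx(c(2700, 4000, 5000, 5500),
                             c(600, 580, 567, 560), xout = cct_label,
                             rule = 2)$y
  pump <- gaussian_line(450, 20)
  phos <- gaussian_line(phos_peak, 110)
  cct_of <- function(r) {
    ct <- cct(light_spectrum(WL_GRID, pump + r * phos))
    if (!is.finite(ct$cct_K)) (if (r > 1) 1000 else 30000) - cct_label
    else ct$cct_K - cct_label
  }
  r <- stats::uniroot(cct_of, c(0.05, 20), tol = 1e-6)$root
  spd <- pump + r * phos
  spd <- spd / max(spd)
  if (is.null(.spectra_env$whites)) .spectra_env$whites <- list()
  .spectra_env$whites[[key]] <- spd
  spd
}

# 15 x 401 basis matrix of unit-amplitude channel spectra
channel_basis <- function(channels = default_channels()) {
  t(vapply(seq_len(nrow(channels)), function(i) {
    if (channels$kind[i] == "narrowband")
      gaussian_line(channels$peak_nm[i], channels$fwhm_nm[i])
    else
      white_channel_spd(channels$cct_label_K[i])
  }, numeric(length(WL_GRID))))
}

#' Mix a spectrum from LED channel weights
#'
#' Weighted sum of the unit-amplitude channel basis spectra on the 1 nm
#' grid. Mixing is linear: `mix_spectrum(w1) + mix_spectrum(w2)` equals
#' `mix_spectrum(w1 + w2)` pointwise.
#'
#' @param weights Non-negative weights, one per channel.
#' @param channels Channel table from [default_channels()].
#' @return A `"light_spectrum"` (zero spectrum for all-zero weights).
#' @export
mix_spectrum <- function(weights, channels = default_channels()) {
  if (length(weights) != nrow(channels))
    stop(sprintf("need %d weights", nrow(channels)), call. = FALSE)
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  le <- as.numeric(weights %*% channel_basis(channels))
  structure(list(wavelength_nm = WL_GRID, radiance = le),
            class = "light_spectrum")
}

#' Solve channel weights for a chromaticity/luminance target
#'
#' Finds non-negative channel weights whose mixture matches a target
#' chromaticity and luminance. Because mixing is linear in tristimulus
#' space, the multi-objective search of the physical luminaire reduces to a
#' non-negative least-squares problem on the channel tristimulus matrix
#' (solved with `pracma::lsqnonneg`), which is deterministic. The achieved
#' metrics are checked against tolerances |du'|, |dv'| <= 1e-3 and
#' |dL|/L <= 0.5%; an unreachable (out-of-gamut) target errors.
#'
#' @param target Either `list(uprime =, vprime =, luminance =)` or
#'   `list(cct =, luminance =)` (the CCT form targets the Planckian-locus
#'   chromaticity at that temperature).
#' @param channels Channel table from [default_channels()].
#' @return Numeric weight vector (length = number of channels) with
#'   attribute `achieved` (the mixture's [stimulus_metrics()]).
#' @export
solve_weights <- function(target, channels = default_channels()) {
  if (!is.null(target$cct)) {
    loc <- planck_locus()
    u <- approx(loc$T, loc$u, xout = target$cct)$y
    v <- approx(loc$T, loc$v, xout = target$cct)$y
    target$uprime <- u
    target$vprime <- 1.5 * v
  }
  up <- target$uprime; vp <- target$vprime; lum <- target$luminance
  if (is.null(up) || is.null(vp) || is.null(lum))
    stop("target must give uprime/vprime (or cct) and luminance",
         call. = FALSE)
  den <- 6 * up - 16 * vp + 12
  x <- 9 * up / den
  y <- 4 * vp / den
  Y0 <- lum / KM_LM_PER_W
  b <- c(x / y * Y0, Y0, (1 - x - y) / y * Y0)

  tab <- action_spectra()
  B <- channel_basis(channels)
  # per-channel tristimulus values (trapezoid on the 1 nm grid)
  tz <- function(v) as.numeric(B %*% v) -
    0.5 * (B[, 1] * v[1] + B[, ncol(B)] * v[length(v)])
  A <- rbind(tz(tab$xbar), tz(tab$ybar), tz(tab$zbar))
  sol <- pracma::lsqnonneg(A / Y0, b / Y0)
  w <- sol$x
  ach <- stimulus_metrics(mix_spectrum(w, channels))
  if (abs(ach$uprime - up) > 1e-3 || abs(ach$vprime - vp) > 1e-3 ||
      abs(ach$luminance - lum) / lum > 0.005)
    stop(sprintf(paste0("target outside the channel gamut: achieved u' %.4f",
                        " v' %.4f L %.1f vs target u' %.4f v' %.4f L %.1f"),
                 ach$uprime, ach$vprime, ach$luminance, up, vp, lum),
         call. = FALSE)
  attr(w, "achieved") <- ach
  w
}

#' The seven emulated study stimuli
#'
#' Builds the stimulus set of the emulated experiments at a common
#' luminance: four chromatic stimuli (the 450, 530, 610 and 660 nm channels
#' scaled to the target luminance) and three polychromatic mixtures solved
#' onto the Planckian locus at ~2000 K, ~5000 K and ~10000 K.
#'
#' @param luminance_cdm2 Common stimulus luminance (default 100 cd/m^2).
#' @return Named list of [stimulus_metrics()] objects
#'   (`led450` ... `cct10000`).
#' @export
study_stimuli <- function(luminance_cdm2 = 100) {
  ch <- default_channels()
  out <- list()
  for (pk in c(450, 530, 610, 660)) {
    w <- as.numeric(!is.na(ch$peak_nm) & ch$peak_nm == pk)
    s <- mix_spectrum(w, ch)
    s$radiance <- s$radiance * luminance_cdm2 / luminance(s)
    out[[paste0("led", pk)]] <- stimulus_metrics(s)
  }
  for (temp in c(2000, 5000, 10000)) {
    w <- solve_weights(list(cct = temp, luminance = luminance_cdm2), ch)
    out[[paste0("cct", temp)]] <- stimulus_metrics(mix_spectrum(w, ch))
  }
  out
}

#' Subject-level generator parameters
#'
#' Parameters of the didactic pupil-dynamics generator
#' \deqn{d(t) = baseline - A_{phasic} e^{-t/\tau_{phasic}}
#'   - g_{mel} E_{mel} (1 - e^{-t/\tau_{redil}})}
#' clipped to [1.5, 9] mm, where \eqn{E_{mel}} is the stimulus melanopic
#' radiance. Defaults emulate a photopic 100 cd/m^2 exposure: a ~0.8 mm
#' phasic constriction decaying over ~1.2 s and a melanopsin-scaled
#' sustained constriction approached with a ~60 s time constant, plus
#' measurement noise, Poisson-scheduled blink dropouts and rare
#' single-sample spikes.
#'
#' @param baseline_diameter_mm Pre-stimulus diameter, mm (4-9).
#' @param phasic_amplitude_mm Amplitude of the transient constriction, mm.
#' @param phasic_tau_s Decay time constant of the transient, s.
#' @param sustained_gain Sustained constriction per unit melanopic radiance
#'   (mm per W m^-2 sr^-1).
#' @param redilation_tau_s Time constant of the sustained component, s.
#' @param noise_sd_mm Per-sample Gaussian measurement noise, mm.
#' @param blink_rate_hz Mean blink rate (Poisson process), Hz.
#' @param blink_duration_ms Mean blink dropout duration, ms.
#' @param spike_rate_hz Rate of single-sample reflection spikes, Hz.
#' @param low_quality_rate_hz Rate of short low-quality episodes, Hz.
#' @param seed Integer seed making the trace bit-reproducible.
#' @return List of class `"subject_params"`.
#' @export
subject_params <- function(baseline_diameter_mm = 5.5,
                           phasic_amplitude_mm = 0.8,
                           phasic_tau_s = 1.2,
                           sustained_gain = 0.6,
                           redilation_tau_s = 60,
                           noise_sd_mm = 0.08,
                           blink_rate_hz = 0.25,
                           blink_duration_ms = 200,
                           spike_rate_hz = 0.015,
                           low_quality_rate_hz = 0.02,
                           seed = 1L) {
  stopifnot(baseline_diameter_mm >= 4, baseline_diameter_mm <= 9,
            phasic_amplitude_mm > 0, phasic_tau_s > 0,
            sustained_gain >= 0, redilation_tau_s > 0,
            noise_sd_mm >= 0, blink_rate_hz >= 0, blink_duration_ms > 0)
  structure(as.list(environment()), class = "subject_params")
}

#' Generate one raw pupil trace with ground truth
#'
#' Simulates the pupil response to a stimulus: the noise-free dynamics of
#' [subject_params()], plus Gaussian measurement noise, Poisson-scheduled
#' blink dropouts (diameter missing, blink flag set, quality drawn low),
#' short low-quality episodes and occasional single-sample spikes. Seeded
#' and bit-reproducible.
#'
#' @param stimulus A [stimulus_metrics()] object, or a bare melanopic
#'   radiance (W m^-2 sr^-1).
#' @param subject A [subject_params()].
#' @param duration_s Trace duration, s (>= 5).
#' @param fs Sampling rate, Hz.
#' @param meta Metadata list stored on the trace.
#' @return List with `raw` (a [pupil_trace()]) and `truth` (list:
#'   `clean_mm` noise-free series, `blink_mask`, `spike_idx`,
#'   `low_quality_idx`, `steady_state_mm` the t -> Inf closed form).
#' @export
generate_trace <- function(stimulus, subject = subject_params(),
                           duration_s = 300, fs = 120, meta = list()) {
  if (duration_s < 5) stop("duration must be >= 5 s", call. = FALSE)
  mel <- if (inherits(stimulus, "stimulus_metrics"))
    stimulus$alpha_opic$melanopic else as.numeric(stimulus)
  p <- subject
  n <- round(duration_s * fs) + 1L
  t <- (seq_len(n) - 1L) / fs

  clean <- p$baseline_diameter_mm -
    p$phasic_amplitude_mm * exp(-t / p$phasic_tau_s) -
    p$sustained_gain * mel * (1 - exp(-t / p$redilation_tau_s))
  clean <- pmin(pmax(clean, 1.5), 9)
  steady <- min(max(p$baseline_diameter_mm - p$sustained_gain * mel, 1.5), 9)

  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    set.seed(p$seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else rm(".Random.seed", envir = globalenv()))
    code
  }
  withr_seed({
    d <- clean + rnorm(n, 0, p$noise_sd_mm)
    quality <- 100 - runif(n) * 2  # healthy samples: 98-100%

    blink_mask <- rep(FALSE, n)
    if (p$blink_rate_hz > 0) {
      n_blinks <- rpois(1, p$blink_rate_hz * duration_s)
      if (n_blinks > 0) {
        starts <- sort(runif(n_blinks, 0, duration_s))
        durs <- rexp(n_blinks, 1000 / p$blink_duration_ms)
        for (j in seq_len(n_blinks)) {
          sel <- t >= starts[j] & t <= starts[j] + durs[j]
          blink_mask[sel] <- TRUE
        }
      }
    }
    d[blink_mask] <- NA_real_
    quality[blink_mask] <- runif(sum(blink_mask), 0, 50)

    low_q_idx <- integer(0)
    if (p$low_quality_rate_hz > 0) {
      n_lq <- rpois(1, p$low_quality_rate_hz * duration_s)
      if (n_lq > 0) {
        lq_start <- sample.int(n, n_lq)
        low_q_idx <- unique(unlist(lapply(lq_start, function(i)
          i:min(n, i + sample.int(12, 1)))))
        low_q_idx <- setdiff(low_q_idx, which(blink_mask))
        quality[low_q_idx] <- runif(length(low_q_idx), 60, 96.9)
        # low-quality samples carry corrupted diameters
        d[low_q_idx] <- d[low_q_idx] + rnorm(length(low_q_idx), 0, 0.5)
      }
    }

    spike_idx <- integer(0)
    if (p$spike_rate_hz > 0) {
      n_spikes <- rpois(1, p$spike_rate_hz * duration_s)
      if (n_spikes > 0) {
        spike_idx <- sample(which(!blink_mask), min(n_spikes,
                                                    sum(!blink_mask)))
        d[spike_idx] <- d[spike_idx] + runif(length(spike_idx), 0.8, 1.2)
      }
    }
    d <- pmin(pmax(d, 0.51), 9.99)

    raw <- pupil_trace(t, d, quality, blink_mask, fs = fs, meta = meta)
    list(raw = raw,
         truth = list(clean_mm = clean, blink_mask = blink_mask,
                      spike_idx = sort(spike_idx),
                      low_quality_idx = sort(low_q_idx),
                      steady_state_mm = steady))
  })
}

#' Generate a synthetic observer cohort
#'
#' Draws per-subject generator parameters around population means
#' (interpersonal scatter `inter_sd_mm` on the baseline diameter,
#' trial-level intrapersonal scatter `intra_sd_mm`) and simulates, for each
#' subject, a randomized stimulus schedule with a re-adaptation anchor
#' trace before every stimulus. Defaults follow the emulated study design:
#' 20 observers, 300 s exposures, anchor before each stimulus, scatter
#' calibrated to the reported +-1.5 mm interpersonal and +-0.3-0.6 mm
#' intrapersonal ranges.
#'
#' @param n Number of subjects.
#' @param stimuli Named list of stimuli: each element a
#'   [stimulus_metrics()] or bare melanopic radiance.
#' @param inter_sd_mm Interpersonal SD of the baseline diameter, mm.
#' @param intra_sd_mm Intrapersonal (trial-to-trial) SD, mm.
#' @param seed Master seed; all per-trace seeds derive from it.
#' @param duration_s,fs Trace duration and sampling rate.
#' @param anchor_stimulus Stimulus driving the anchor traces (default: a
#'   melanopic radiance of 0, i.e. the subject sits at baseline).
#' @param steady_target Optional: named numeric vector (one per stimulus)
#'   of designed steady-state diameters. When given, each subject's
#'   `sustained_gain` is set per stimulus so the noise-free steady diameter
#'   equals `steady_target[stimulus] + N(0, intra_sd_mm)`.
#' @param subject_template A [subject_params()] giving population means.
#' @return List of class `"synthetic_cohort"`: `subjects` (per-subject
#'   parameter list), `recordings` (list of records with `subject`,
#'   `stimulus`, `role` ("anchor"/"stimulus"), `raw`, `truth`), and the
#'   call parameters.
#' @export
generate_cohort <- function(n = 20, stimuli, inter_sd_mm = 0.75,
                            intra_sd_mm = 0.3, seed = 42L,
                            duration_s = 300, fs = 120,
                            anchor_stimulus = 0,
                            steady_target = NULL,
                            subject_template = subject_params()) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (is.null(names(stimuli)) || any(names(stimuli) == ""))
    stop("'stimuli' must be a named list", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))

  mel_of <- function(s) if (inherits(s, "stimulus_metrics"))
    s$alpha_opic$melanopic else as.numeric(s)

  subjects <- lapply(seq_len(n), function(i) {
    p <- subject_template
    p$baseline_diameter_mm <- min(max(
      p$baseline_diameter_mm + rnorm(1, 0, inter_sd_mm), 4), 9)
    p$subject_id <- sprintf("s%02d", i)
    p
  })

  recordings <- list()
  for (i in seq_len(n)) {
    p <- subjects[[i]]
    order_i <- sample(names(stimuli))
    for (lab in order_i) {
      # anchor preceding the stimulus
      pa <- p
      pa$seed <- sample.int(.Machine$integer.max, 1)
      rec_a <- generate_trace(anchor_stimulus, pa, duration_s, fs,
                              meta = list(subject = p$subject_id,
                                          stimulus = lab, role = "anchor"))
      ps <- p
      ps$seed <- sample.int(.Machine$integer.max, 1)
      mel <- mel_of(stimuli[[lab]])
      if (!is.null(steady_target)) {
        tgt <- steady_target[[lab]] + rnorm(1, 0, intra_sd_mm)
        if (mel <= 0) stop("steady_target needs melanopic > 0", call. = FALSE)
        ps$sustained_gain <- (ps$baseline_diameter_mm - tgt) / mel
      } else {
        ps$baseline_diameter_mm <- min(max(
          ps$baseline_diameter_mm + rnorm(1, 0, intra_sd_mm), 4), 9)
      }
      rec_s <- generate_trace(stimuli[[lab]], ps, duration_s, fs,
                              meta = list(subject = p$subject_id,
                                          stimulus = lab, role = "stimulus"))
      recordings <- c(recordings, list(
        c(list(subject = p$subject_id, stimulus = lab, role = "anchor"),
          rec_a),
        c(list(subject = p$subject_id, stimulus = lab, role = "stimulus"),
          rec_s)))
    }
  }
  structure(list(subjects = subjects, recordings = recordings,
                 stimuli = names(stimuli), n = n, seed = seed,
                 duration_s = duration_s, fs = fs),
            class = "synthetic_cohort")
}
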