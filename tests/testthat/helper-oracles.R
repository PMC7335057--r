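# Independent oracles used by the tests. Each is written from first
# principles (explicit loops, definitional formulas) and never calls the
# package code path it checks.

# One-way within-subject ANOVA from the definitional sums of squares and
# the normalized-Helmert contrast covariance (Mauchly W, GG epsilon).
rm_anova_oracle <- function(y) {
  y <- as.matrix(y)
  n <- nrow(y); k <- ncol(y)
  grand <- mean(y)
  ss_subj <- 0
  for (i in 1:n) ss_subj <- ss_subj + k * (mean(y[i, ]) - grand)^2
  ss_cond <- 0
  for (j in 1:k) ss_cond <- ss_cond + n * (mean(y[, j]) - grand)^2
  ss_tot <- 0
  for (i in 1:n) for (j in 1:k) ss_tot <- ss_tot + (y[i, j] - grand)^2
  ss_err <- ss_tot - ss_subj - ss_cond
  f <- (ss_cond / (k - 1)) / (ss_err / ((n - 1) * (k - 1)))

  # sample covariance, explicit loops
  Sig <- matrix(0, k, k)
  for (a in 1:k) for (b in 1:k)
    Sig[a, b] <- sum((y[, a] - mean(y[, a])) * (y[, b] - mean(y[, b]))) /
      (n - 1)
  # normalized Helmert contrasts (orthonormal, orthogonal to unit vector)
  C <- matrix(0, k, k - 1)
  for (j in 1:(k - 1)) {
    C[1:j, j] <- 1 / sqrt(j * (j + 1))
    C[j + 1, j] <- -j / sqrt(j * (j + 1))
  }
  S1 <- t(C) %*% Sig %*% C
  w <- det(S1) / (sum(diag(S1)) / (k - 1))^(k - 1)
  eps <- sum(diag(S1))^2 / ((k - 1) * sum(S1 * S1))
  # plain chi-square approximation to Mauchly's statistic
  dd <- 1 - (2 * (k - 1)^2 + (k - 1) + 2) / (6 * (k - 1) * (n - 1))
  chi2 <- -(n - 1) * dd * log(w)
  p <- pchisq(chi2, k * (k - 1) / 2 - 1, lower.tail = FALSE)
  list(f = f, w = w, eps = eps, chi2 = chi2, p = p,
       ss = c(subject = ss_subj, condition = ss_cond, error = ss_err))
}

# noise-free generator dynamics recomputed from the closed form
dynamics_oracle <- function(t, p, mel) {
  pmin(pmax(p$baseline_diameter_mm -
              p$phasic_amplitude_mm * exp(-t / p$phasic_tau_s) -
              p$sustained_gain * mel * (1 - exp(-t / p$redilation_tau_s)),
            1.5), 9)
}

# fine-grid trapezoid of f(lambda) * spline-interpolated action spectrum
fine_integral_oracle <- function(radiance_fun, column, step = 0.05) {
  tab <- pupilbench::action_spectra()
  wl <- seq(380, 780, by = step)
  s <- spline(tab$wavelength_nm, tab[[column]], xout = wl)$y
  y <- radiance_fun(wl) * s
  (sum(y) - (y[1] + y[length(y)]) / 2) * step
}

gaussian_fwhm_sd <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

make_constant_trace <- function(value = 4, n = 1200, fs = 120) {
  pupil_trace((seq_len(n) - 1) / fs, rep(value, n), fs = fs)
}
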