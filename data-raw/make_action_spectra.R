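# Generates inst/extdata/action_spectra_synthetic.csv, the bundled observer /
# receptor tabulations on a 1 nm grid (380-780 nm).
#
# These are ANALYTIC APPROXIMATIONS, not the official CIE tables:
#   * CIE 1931 2-deg color-matching functions: multi-lobe piecewise-Gaussian
#     fits of Wyman, Sloan & Shirley (J. Computer Graphics Techniques, 2013),
#     rescaled so the three integrals over 380-780 nm are exactly equal
#     (preserving the equal-energy x = y = 1/3 identity of the true tables).
#   * V(lambda): the fitted ybar, peak-normalized.
#   * Receptor (alpha-opic style) action spectra: Govardovskii et al. (2000)
#     A1 visual-pigment nomograms positioned at the peak wavelengths of the
#     corresponding CIE S 026 alpha-opic action spectra (S 448, M 542, L 570,
#     melanopic 490 nm), peak-normalized.
# The "_synthetic" suffix marks the file as a constructed stand-in.

gauss2 <- function(x, mu, s1, s2) {
  s <- ifelse(x < mu, s1, s2)
  exp(-((x - mu)^2) / (2 * s^2))
}

wl <- 380:780

xbar <- 1.056 * gauss2(wl, 599.8, 37.9, 31.0) +
        0.362 * gauss2(wl, 442.0, 16.0, 26.7) -
        0.065 * gauss2(wl, 501.1, 20.4, 26.2)
ybar <- 0.821 * gauss2(wl, 568.8, 46.9, 40.5) +
        0.286 * gauss2(wl, 530.9, 16.3, 31.1)
zbar <- 1.217 * gauss2(wl, 437.0, 11.8, 36.0) +
        0.681 * gauss2(wl, 459.0, 26.0, 13.8)
xbar <- pmax(xbar, 0)

# equalize integrals (trapezoid, 1 nm) so equal-energy white maps to (1/3, 1/3)
trap <- function(y) sum(y) - (y[1] + y[length(y)]) / 2
iy <- trap(ybar)
xbar <- xbar * iy / trap(xbar)
zbar <- zbar * iy / trap(zbar)

vlambda <- ybar / max(ybar)

# Govardovskii A1 template (alpha + beta band), peak-normalized
pigment <- function(wl, lmax) {
  x <- lmax / wl
  a <- 0.8795 + 0.0459 * exp(-(lmax - 300)^2 / 11940)
  s_alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                  exp(-14.9 * (1.104 - x)) + 0.674)
  lmb <- 189 + 0.315 * lmax
  b <- -40.5 + 0.195 * lmax
  s_beta <- 0.26 * exp(-((wl - lmb) / b)^2)
  s <- s_alpha + s_beta
  s / max(s)
}

tab <- data.frame(
  wavelength_nm = wl,
  xbar = xbar, ybar = ybar, zbar = zbar,
  vlambda = vlambda,
  s_cone = pigment(wl, 448),
  m_cone = pigment(wl, 542),
  l_cone = pigment(wl, 570),
  melanopic = pigment(wl, 490)
)

tab[-1] <- lapply(tab[-1], signif, digits = 7)
dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
write.csv(tab, "inst/extdata/action_spectra_synthetic.csv",
          row.names = FALSE, quote = FALSE)
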