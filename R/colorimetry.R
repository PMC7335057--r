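# Spectral characterization of stimuli: luminance, chromaticity, CCT and
# receptor-weighted (alpha-opic style) radiances. All integrals are
# trapezoidal on a common 1 nm grid (380-780 nm); wavelengths outside the
# input range contribute zero.

WL_GRID <- 380:780
KM_LM_PER_W <- 683  # maximum luminous efficacy, lm/W

# trapezoid integral on the uniform 1 nm grid
trapz1 <- function(y) sum(y) - (y[1] + y[length(y)]) / 2

#' Spectral radiance distribution
#'
#' Validates and resamples a spectral radiance distribution onto the
#' package's common 1 nm grid (380-780 nm). Input wavelengths must be
#' strictly increasing and should cover at least 400-700 nm (the effective
#' support of the luminous efficiency function); values outside the input
#' range are treated as zero.
#'
#' @param wavelength_nm Strictly increasing wavelengths in nm.
#' @param radiance Non-negative spectral radiance, W m^-2 sr^-1 nm^-1.
#' @return Object of class `"light_spectrum"`: list with `wavelength_nm`
#'   (the 1 nm grid) and `radiance`.
#' @examples
#' s <- light_spectrum(seq(380, 780, 5), rep(1, 81))  # equal-energy
#' luminance(s)
#' @export
light_spectrum <- function(wavelength_nm, radiance) {
  wl <- as.numeric(wavelength_nm); le <- as.numeric(radiance)
  if (length(wl) != length(le))
    stop("wavelength and radiance lengths differ", call. = FALSE)
  if (length(wl) < 2)
    stop("a spectrum needs at least two samples to integrate", call. = FALSE)
  if (any(diff(wl) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (any(!is.finite(le)) || any(le < 0))
    stop("radiance must be finite and non-negative", call. = FALSE)
  if (wl[1] > 400 || wl[length(wl)] < 700)
    stop("spectrum misses the V(lambda) support (must cover 400-700 nm)",
         call. = FALSE)
  if (max(diff(wl)) > 5 + 1e-9)
    warning("input grid coarser than 5 nm; resampling accuracy not guaranteed",
            call. = FALSE)
  le1 <- approx(wl, le, xout = WL_GRID, yleft = 0, yright = 0)$y
  structure(list(wavelength_nm = WL_GRID, radiance = le1),
            class = "light_spectrum")
}

as_spectrum <- function(x) {
  if (inherits(x, "light_spectrum")) x
  else stop("expected a light_spectrum object", call. = FALSE)
}

#' Monochromatic line spectrum
#'
#' A single 1-nm-wide line at `wavelength_nm` carrying `radiance`
#' W m^-2 sr^-1 (so the trapezoid integral of the line equals `radiance`).
#'
#' @param wavelength_nm Line position in nm (within 381-779).
#' @param radiance Integrated line radiance, W m^-2 sr^-1.
#' @return A `"light_spectrum"`.
#' @export
monochromatic_spectrum <- function(wavelength_nm, radiance = 1) {
  le <- numeric(length(WL_GRID))
  i <- which.min(abs(WL_GRID - wavelength_nm))
  le[i] <- radiance
  structure(list(wavelength_nm = WL_GRID, radiance = le),
            class = "light_spectrum")
}

#' Planckian (blackbody) radiator spectrum
#'
#' Spectral radiance of a blackbody at temperature `temp_K` on the 1 nm
#' grid, optionally rescaled to a given photopic luminance.
#'
#' @param temp_K Temperature in kelvin.
#' @param luminance_cdm2 If not `NULL`, scale so [luminance()] equals this.
#' @return A `"light_spectrum"`.
#' @export
planck_spectrum <- function(temp_K, luminance_cdm2 = NULL) {
  lam <- WL_GRID * 1e-9
  c2 <- 1.4388e-2  # m K
  le <- 1 / (lam^5 * (exp(c2 / (lam * temp_K)) - 1))
  le <- le / max(le)
  s <- structure(list(wavelength_nm = WL_GRID, radiance = le),
                 class = "light_spectrum")
  if (!is.null(luminance_cdm2)) {
    lv <- luminance(s)
    if (lv <= 0) stop("cannot scale a zero-luminance spectrum", call. = FALSE)
    s$radiance <- s$radiance * luminance_cdm2 / lv
  }
  s
}

#' Photopic luminance of a spectrum
#'
#' \eqn{L_v = 683 \int V(\lambda) L_e(\lambda) d\lambda} in cd/m^2,
#' trapezoidal on the 1 nm grid.
#'
#' @param spec A [light_spectrum()].
#' @return Luminance in cd/m^2.
#' @export
luminance <- function(spec) {
  spec <- as_spectrum(spec)
  KM_LM_PER_W * trapz1(action_spectra()$vlambda * spec$radiance)
}

#' Chromaticity coordinates of a spectrum
#'
#' CIE 1931 (x, y) from the color-matching-function integrals and the
#' CIE 1976 projective transform
#' \eqn{u' = 4x / (-2x + 12y + 3)}, \eqn{v' = 9y / (-2x + 12y + 3)}.
#'
#' @param spec A [light_spectrum()].
#' @return Named list `x`, `y`, `uprime`, `vprime`.
#' @export
chromaticity <- function(spec) {
  spec <- as_spectrum(spec)
  tab <- action_spectra()
  X <- trapz1(tab$xbar * spec$radiance)
  Y <- trapz1(tab$ybar * spec$radiance)
  Z <- trapz1(tab$zbar * spec$radiance)
  s <- X + Y + Z
  if (s <= 0)
    stop("chromaticity undefined for a zero spectrum", call. = FALSE)
  x <- X / s; y <- Y / s
  den <- -2 * x + 12 * y + 3
  list(x = x, y = y, uprime = 4 * x / den, vprime = 9 * y / den)
}

# Planckian locus lookup table in CIE 1960 (u, v) space, ~1% temperature
# steps over 1000-20050 K; cached after first use.
planck_locus <- function() {
  if (is.null(.spectra_env$locus)) {
    temps <- 1000 * 1.01^(0:302)
    uv <- vapply(temps, function(tt) {
      ch <- chromaticity(planck_spectrum(tt))
      c(ch$uprime, 2 / 3 * ch$vprime)
    }, numeric(2))
    .spectra_env$locus <- list(T = temps, u = uv[1, ], v = uv[2, ])
  }
  .spectra_env$locus
}

#' Correlated color temperature and Planckian-locus distance
#'
#' Nearest-Planckian-locus temperature found on a fine lookup table
#' (about 1% temperature steps, 1000-20000 K) with local parabolic
#' refinement. The distance is measured in the CIE 1960 (u, 2v'/3) plane;
#' `duv` is signed (positive above the locus). Following common practice
#' the CCT is flagged undefined when |duv| > 0.05.
#'
#' @param x A [light_spectrum()] or a named list/vector with `uprime`,
#'   `vprime` chromaticity coordinates.
#' @return List `cct_K` (NA when undefined), `duv`, `defined`.
#' @export
cct <- function(x) {
  if (inherits(x, "light_spectrum")) x <- chromaticity(x)
  u <- x[["uprime"]]; v <- 2 / 3 * x[["vprime"]]
  loc <- planck_locus()
  d2 <- (loc$u - u)^2 + (loc$v - v)^2
  i <- which.min(d2)
  if (i > 1 && i < length(d2)) {
    # parabolic refinement of squared distance over the index
    a <- d2[i - 1]; b <- d2[i]; c2_ <- d2[i + 1]
    denom <- a - 2 * b + c2_
    frac <- if (denom > 0) 0.5 * (a - c2_) / denom else 0
    frac <- max(-0.5, min(0.5, frac))
    temp <- 1000 * 1.01^((i - 1) + frac)
    ulo <- approx(seq_along(loc$u), loc$u, xout = i + frac)$y
    vlo <- approx(seq_along(loc$v), loc$v, xout = i + frac)$y
  } else {
    temp <- loc$T[i]; ulo <- loc$u[i]; vlo <- loc$v[i]
  }
  duv <- sqrt((u - ulo)^2 + (v - vlo)^2) * sign(v - vlo)
  defined <- is.finite(duv) && abs(duv) <= 0.05 &&
    i > 1 && i < length(d2)
  list(cct_K = if (defined) temp else NA_real_, duv = duv, defined = defined)
}

#' Receptor-weighted (alpha-opic) radiances
#'
#' Integrates the spectrum against the peak-normalized S-, M-, L-cone and
#' melanopic action spectra, returning radiances in W m^-2 sr^-1 (the
#' convention of the CIE S 026 alpha-opic radiance).
#'
#' @param spec A [light_spectrum()].
#' @return Named list `s_cone`, `m_cone`, `l_cone`, `melanopic`.
#' @export
alpha_opic <- function(spec) {
  spec <- as_spectrum(spec)
  tab <- action_spectra()
  lapply(setNames(nm = c("s_cone", "m_cone", "l_cone", "melanopic")),
         function(col) trapz1(tab[[col]] * spec$radiance))
}

#' Full stimulus characterization
#'
#' Computes every per-stimulus metric used by the benchmark: luminance,
#' CIE 1931 (x, y), CIE 1976 (u', v'), CCT with signed duv, and the four
#' receptor-weighted radiances.
#'
#' @param spec A [light_spectrum()].
#' @return Object of class `"stimulus_metrics"`.
#' @export
stimulus_metrics <- function(spec) {
  spec <- as_spectrum(spec)
  lv <- luminance(spec)
  ch <- chromaticity(spec)
  ct <- cct(ch)
  structure(c(list(luminance = lv), ch, ct,
              list(alpha_opic = alpha_opic(spec))),
            class = "stimulus_metrics")
}

#' @export
print.stimulus_metrics <- function(x, ...) {
  cat(sprintf("luminance: %.2f cd/m^2\n", x$luminance))
  cat(sprintf("chromaticity: x %.4f  y %.4f  u' %.4f  v' %.4f\n",
              x$x, x$y, x$uprime, x$vprime))
  if (x$defined)
    cat(sprintf("CCT: %.0f K (duv %+.4f)\n", x$cct_K, x$duv))
  else
    cat(sprintf("CCT: undefined (duv %+.3f)\n", x$duv))
  ao <- x$alpha_opic
  cat(sprintf(
    "receptor radiances (W m^-2 sr^-1): S %.4g  M %.4g  L %.4g  mel %.4g\n",
    ao$s_cone, ao$m_cone, ao$l_cone, ao$melanopic))
  invisible(x)
}
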