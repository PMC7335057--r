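# Bundled observer and receptor tabulations.
#
# inst/extdata/action_spectra_synthetic.csv holds, on a 1 nm grid
# (380-780 nm): CIE-1931-style 2-deg color-matching functions (analytic
# multi-lobe Gaussian fits, integrals equalized), V(lambda) (peak-normalized
# ybar), and receptor action spectra in the CIE S 026 alpha-opic style
# (A1 pigment nomograms positioned at the S-cone-opic 448 nm, M-cone-opic
# 542 nm, L-cone-opic 570 nm and melanopic 490 nm peaks, peak-normalized).
# The "_synthetic" suffix flags that these are constructed approximations to
# the published tabulations, not the official tables; see data-raw/.

.spectra_env <- new.env(parent = emptyenv())

#' Bundled action-spectra table
#'
#' Returns the packaged observer/receptor tabulation used by all
#' colorimetric integrals: wavelength (nm, 1 nm grid, 380-780),
#' color-matching functions `xbar`, `ybar`, `zbar`, the photopic luminous
#' efficiency function `vlambda` (unit peak), and the peak-normalized
#' receptor action spectra `s_cone`, `m_cone`, `l_cone`, `melanopic`.
#' The tables are analytic approximations to the standard published
#' tabulations (see the package vignette for provenance and accuracy notes).
#'
#' @return A data.frame with 401 rows and 9 columns.
#' @export
action_spectra <- function() {
  if (is.null(.spectra_env$tab)) {
    path <- system.file("extdata", "action_spectra_synthetic.csv",
                        package = "pupilbench", mustWork = TRUE)
    .spectra_env$tab <- read.csv(path)
  }
  .spectra_env$tab
}
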