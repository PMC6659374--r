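#' First-order multiplet pattern from J-couplings
#'
#' Builds the line positions and relative intensities of a first-order
#' multiplet by iterated convolution: each coupling to `m` equivalent
#' partners splits every line into an (m+1)-line pattern with binomial
#' weights and spacing `J_hz / frequency_mhz` ppm. Strong-coupling
#' (second-order) distortions are deliberately not modelled.
#'
#' @param couplings List of `c(J_hz, m)` pairs; empty list gives a singlet.
#' @param frequency_mhz Spectrometer frequency (MHz), converts Hz to ppm.
#' @return data.frame with columns `offset_ppm` (centred on 0, symmetric)
#'   and `weight` (sums to 1), ordered by offset.
#' @examples
#' multiplet_pattern(list(c(7.0, 1)), 600)   # doublet at +/- J/2
#' multiplet_pattern(list(c(7.0, 3)), 600)   # 1:3:3:1 quartet
#' @export
multiplet_pattern <- function(couplings, frequency_mhz) {
  stopifnot(frequency_mhz > 0)
  offs <- 0
  wts <- 1
  for (cp in couplings) {
    j_ppm <- cp[1] / frequency_mhz
    m <- as.integer(cp[2])
    if (cp[1] < 0 || m < 1) stop("couplings need J_hz >= 0 and m >= 1")
    k <- 0:m
    sub_off <- (k - m / 2) * j_ppm
    sub_wt <- choose(m, k) / 2^m
    offs <- as.vector(outer(offs, sub_off, `+`))
    wts <- as.vector(outer(wts, sub_wt, `*`))
  }
  # merge numerically coincident lines (e.g. central lines of J,2J pairs)
  # without degrading offset precision
  fac <- factor(round(offs, 12))
  out <- data.frame(
    offset_ppm = as.numeric(tapply(offs, fac, `[`, 1)),
    weight = as.numeric(rowsum(wts, fac)))
  out <- out[order(out$offset_ppm), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Lorentzian line shape
#'
#' `I(d) = (2 area / (pi fwhm)) / (1 + (2 (d - center) / fwhm)^2)`; the
#' analytic integral over the whole axis equals `area`.
#'
#' @param ppm_axis Numeric axis (any order).
#' @param center_ppm Line centre.
#' @param area Integrated area (spectrum units x ppm).
#' @param fwhm_ppm Full width at half maximum (> 0).
#' @return Intensity vector along `ppm_axis`.
#' @export
lorentzian <- function(ppm_axis, center_ppm, area, fwhm_ppm) {
  if (!is.finite(fwhm_ppm) || fwhm_ppm <= 0)
    stop("fwhm_ppm must be positive")
  (2 * area / (pi * fwhm_ppm)) /
    (1 + (2 * (ppm_axis - center_ppm) / fwhm_ppm)^2)
}
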