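#' Area-parameterized pseudo-Voigt profile
#'
#' The pseudo-Voigt lineshape is the eta-weighted sum of a Lorentzian and a
#' Gaussian sharing one center and FWHM:
#' \deqn{pV(E) = A [\eta L(E) + (1 - \eta) G(E)]}
#' where L and G are each normalized to unit integral, so the profile's
#' total integral is exactly `area` for any mixing. Closed-form peak
#' heights: a pure Gaussian (eta = 0) has height
#' `area * (2 / fwhm) * sqrt(ln 2 / pi)`; a pure Lorentzian (eta = 1) has
#' height `2 * area / (pi * fwhm)`.
#'
#' @param energy Energies (eV) at which to evaluate.
#' @param center Peak center (eV).
#' @param fwhm Full width at half maximum (eV), > 0.
#' @param eta Lorentzian fraction in `[0, 1]`.
#' @param area Integrated intensity (normalized-intensity x eV), >= 0.
#' @return Profile values, same length as `energy`.
#' @examples
#' e <- seq(2466, 2474, by = 0.01)
#' y <- pseudo_voigt(e, center = 2470.2, fwhm = 1.1, eta = 0.5, area = 2.03)
#' @export
pseudo_voigt <- function(energy, center, fwhm, eta, area) {
  if (fwhm <= 0) stop("fwhm must be > 0")
  if (eta < 0 || eta > 1) stop("eta must be in [0, 1]")
  if (area < 0) stop("area must be >= 0")
  area * pv_unit(energy, center, fwhm, eta)
}

# Unit-area pseudo-Voigt; no argument checks (inner loop of the fitter).
pv_unit <- function(energy, center, fwhm, eta) {
  sg <- fwhm / (2 * sqrt(2 * log(2)))
  hw <- fwhm / 2
  g <- exp(-((energy - center)^2) / (2 * sg^2)) / (sg * sqrt(2 * pi))
  l <- hw / (pi * ((energy - center)^2 + hw^2))
  eta * l + (1 - eta) * g
}
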