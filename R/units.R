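#' Convert wavelength to wavenumber (and back)
#'
#' The two descriptions of an optical axis used throughout the package.
#' Vibronic spacings are additive in energy, so every internal axis is a
#' strictly ascending wavenumber grid in cm^-1; wavelength (nm) appears only
#' at I/O boundaries. The conversion is the involution \eqn{\tilde\nu = 10^7/\lambda}.
#'
#' @param nm Wavelength(s) in nanometres, strictly positive.
#' @param wavenumber Wavenumber(s) in cm^-1, strictly positive.
#' @return Numeric vector of the converted values.
#' @examples
#' wavelength_to_wavenumber(625) # 16000 cm^-1
#' wavenumber_to_wavelength(10000) # 1000 nm
#' @export
wavelength_to_wavenumber <- function(nm) {
  if (any(!is.finite(nm)) || any(nm <= 0)) {
    stop("wavelengths must be finite and strictly positive", call. = FALSE)
  }
  1e7 / nm
}

#' @rdname wavelength_to_wavenumber
#' @export
wavenumber_to_wavelength <- function(wavenumber) {
  if (any(!is.finite(wavenumber)) || any(wavenumber <= 0)) {
    stop("wavenumbers must be finite and strictly positive", call. = FALSE)
  }
  1e7 / wavenumber
}

# Physical constants used across modules.
# hbar in eV fs; c in cm/fs; 1 cm^-1 in eV.
.hbar_ev_fs <- 0.6582119569
.c_cm_fs <- 2.99792458e-5
.cm1_to_ev <- 1.239841984e-4

#' Second Legendre polynomial
#'
#' \eqn{P_2(x) = (3x^2 - 1)/2}, the workhorse of all photoselection weights.
#'
#' @param x Numeric vector.
#' @return \eqn{(3x^2-1)/2}.
#' @export
legendre_p2 <- function(x) (3 * x^2 - 1) / 2
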