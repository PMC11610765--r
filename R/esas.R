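#' Excited-state spectrum by ground-state-bleach subtraction
#'
#' The ground-state bleach in a TA slice is approximated by a scaled steady
#' state absorption spectrum; since bleach is negative in delta-A, adding
#' `scale * absorption` removes it, leaving only excited-state contributions
#' (stimulated emission and excited-state absorption). In `scale = "auto"`
#' mode the scale is chosen so the result vanishes at a user-named anchor
#' wavenumber where only bleach contributes (by default pick the blue edge of
#' the lowest-energy bleach).
#'
#' @param ta_slice Spectrum tibble of delta-A at one delay.
#' @param absorption Steady-state absorption spectrum on the same axis.
#' @param scale Numeric scale s, or "auto".
#' @param anchor Anchor wavenumber (cm^-1), required for auto scaling.
#' @return Spectrum tibble (domain "delta_A") with attribute `gsb_scale`.
#' @export
subtract_gsb <- function(ta_slice, absorption, scale = "auto", anchor = NULL) {
  .check_same_axis(ta_slice, absorption, "TA slice and absorption spectrum")
  if (identical(scale, "auto")) {
    if (is.null(anchor)) stop("auto scaling needs an anchor wavenumber", call. = FALSE)
    ax <- ta_slice$wavenumber
    if (anchor < min(ax) || anchor > max(ax)) {
      stop("anchor lies outside the spectrum axis", call. = FALSE)
    }
    j <- which.min(abs(ax - anchor))
    if (abs(absorption$value[[j]]) < 1e-12 * max(abs(absorption$value))) {
      stop("absorption vanishes at the anchor; choose a bleach-dominated point",
           call. = FALSE)
    }
    scale <- -ta_slice$value[[j]] / absorption$value[[j]]
  }
  out <- spectrum_tbl(ta_slice$wavenumber,
                      ta_slice$value + scale * absorption$value,
                      domain = "delta_A")
  attr(out, "gsb_scale") <- scale
  attr(out, "delay") <- attr(ta_slice, "delay")
  out
}

#' Stick spectra of computed excited-state transitions
#'
#' @param energies Transition energies, cm^-1.
#' @param strengths Oscillator strengths >= 0.
#' @param origin_state Label of the emitting state ("Qx" or "Qy").
#' @return An `esa_sticks` tibble (`energy`, `strength`) with attribute
#'   `origin_state`.
#' @export
esa_sticks <- function(energies, strengths, origin_state = "Qy") {
  if (length(energies) != length(strengths)) {
    stop("energies and strengths must have equal length", call. = FALSE)
  }
  if (any(strengths < 0)) stop("oscillator strengths must be >= 0", call. = FALSE)
  out <- tibble::tibble(energy = as.numeric(energies),
                        strength = as.numeric(strengths))
  attr(out, "origin_state") <- origin_state
  out
}

#' Read stick spectra from two-column CSV (energy_cm1, strength)
#'
#' @param path CSV/whitespace file, comments with `#`.
#' @param origin_state Label attached to the result.
#' @return An `esa_sticks` tibble.
#' @export
read_esa_sticks <- function(path, origin_state = "Qy") {
  d <- utils::read.table(path, comment.char = "#", sep = "",
                         col.names = c("energy", "strength"))
  esa_sticks(d$energy, d$strength, origin_state)
}

#' Broaden stick spectra into a continuous overlay
#'
#' Sum of unit-normalised Gaussians at the stick energies weighted by the
#' strengths, so the integral equals `sum(strengths) * sigma * sqrt(2*pi)`.
#'
#' @param sticks An [esa_sticks()] tibble.
#' @param sigma Gaussian width, cm^-1.
#' @param axis Wavenumber grid; default spans the sticks +- 4 sigma.
#' @return Spectrum tibble.
#' @export
broaden_sticks <- function(sticks, sigma, axis = NULL) {
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (is.null(axis)) {
    axis <- seq(min(sticks$energy) - 4 * sigma, max(sticks$energy) + 4 * sigma,
                length.out = 512)
  }
  val <- rep(0, length(axis))
  for (i in seq_len(nrow(sticks))) {
    val <- val + sticks$strength[[i]] *
      exp(-(axis - sticks$energy[[i]])^2 / (2 * sigma^2))
  }
  spectrum_tbl(axis, val, domain = "absorbance")
}
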