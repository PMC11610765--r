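#' Fundamental anisotropy of a photoselected transition
#'
#' For an isotropic ensemble, a transition whose TDM makes an angle delta with
#' the reference (pumped or emissive) TDM contributes anisotropy
#' \eqn{r_0 = 0.4 \, P_2(\cos\delta) \in [-0.2, 0.4]}.
#'
#' @param delta_deg Angle in degrees, in `[0, 180]`.
#' @return Fundamental anisotropy value(s).
#' @examples
#' fundamental_anisotropy(0)      # 0.4
#' fundamental_anisotropy(90)     # -0.2
#' fundamental_anisotropy(54.7356) # ~0 (magic angle)
#' @export
fundamental_anisotropy <- function(delta_deg) {
  if (any(delta_deg < 0 | delta_deg > 180)) {
    stop("delta must lie in [0, 180] degrees", call. = FALSE)
  }
  0.4 * legendre_p2(cos(delta_deg * pi / 180))
}

# photoselection weights applied to a species at angle delta (deg) to the
# pumped TDM, for the three probe polarizations
.pol_factor <- function(delta_deg, polarization) {
  p2 <- legendre_p2(cos(delta_deg * pi / 180))
  switch(polarization,
    parallel = 1 + 0.8 * p2,
    perpendicular = 1 - 0.4 * p2,
    magic = rep(1, length(p2))[seq_along(p2)] * 1,
    stop("unknown polarization ", polarization, call. = FALSE)
  )
}

#' Anisotropy from a polarized pair of spectra
#'
#' \eqn{r = (I_\parallel - I_\perp) / (I_\parallel + 2 I_\perp)}. Points where
#' the isotropic intensity falls below `mask_threshold` times its maximum are
#' masked (flagged invalid), never interpolated over.
#'
#' @param parallel,perpendicular Spectrum tibbles on identical axes.
#' @param mask_threshold Low-intensity mask level, fraction of max |I_iso|.
#' @return Anisotropy tibble with columns `wavenumber`, `r`, `mask`
#'   (TRUE = valid).
#' @export
anisotropy_from_pair <- function(parallel, perpendicular, mask_threshold = 1e-3) {
  .check_same_axis(parallel, perpendicular, "polarized spectra")
  denom <- parallel$value + 2 * perpendicular$value
  mask <- abs(denom) >= mask_threshold * max(abs(denom))
  r <- rep(NA_real_, length(denom))
  r[mask] <- (parallel$value[mask] - perpendicular$value[mask]) / denom[mask]
  tibble::tibble(wavenumber = parallel$wavenumber, r = r, mask = mask)
}

#' Isotropic (magic-angle) signal from a polarized pair
#'
#' \eqn{I_{MA} = (I_\parallel + 2 I_\perp)/3}, the polarization-free signal.
#'
#' @inheritParams anisotropy_from_pair
#' @return Spectrum tibble.
#' @export
magic_from_pair <- function(parallel, perpendicular) {
  .check_same_axis(parallel, perpendicular, "polarized spectra")
  spectrum_tbl(parallel$wavenumber,
               (parallel$value + 2 * perpendicular$value) / 3,
               domain = attr(parallel, "domain") %||% "delta_A")
}

#' Rotated decomposition frame
#'
#' The frame angle beta rotates an orthogonal molecular coordinate system
#' relative to the reference TDM, accommodating transitions separated by
#' theta = 90 - beta degrees rather than exactly 90. The two components carry
#' anisotropies \eqn{r_p = 0.4 P_2(\cos\beta)} (reference-aligned slot) and
#' \eqn{r_o = 0.4 P_2(\cos(90-\beta))} (rotated-orthogonal slot).
#'
#' @param beta_deg Frame angle beta in degrees, `[0, 45)`.
#' @return List with `beta`, `r_parallel`, `r_orthogonal`, `theta`
#'   (= 90 - beta, the accommodated TDM separation).
#' @export
decomposition_frame <- function(beta_deg) {
  if (beta_deg < 0 || beta_deg >= 45) {
    stop("beta must lie in [0, 45) degrees (the frame degenerates at 45)",
         call. = FALSE)
  }
  r_p <- fundamental_anisotropy(beta_deg)
  r_o <- fundamental_anisotropy(90 - beta_deg)
  list(beta = beta_deg, r_parallel = r_p, r_orthogonal = r_o, theta = 90 - beta_deg)
}

#' Decompose an isotropic spectrum into polarization-associated components
#'
#' Two-component intensity-weighted decomposition: with frame anisotropies
#' r_p and r_o (see [decomposition_frame()]),
#' \deqn{S_\parallel = S_{iso} (r - r_o)/(r_p - r_o), \quad
#'       S_\perp = S_{iso} - S_\parallel.}
#' The two components sum back to the input exactly at every unmasked point.
#' A species whose TDM sits at angle delta to the reference vanishes from
#' `s_orthogonal` when beta = delta and from `s_parallel` when beta = 90 - delta.
#'
#' @param s_iso Isotropic spectrum tibble.
#' @param r Anisotropy tibble from [anisotropy_from_pair()] (same axis).
#' @param beta_deg Frame angle, degrees in `[0, 45)`.
#' @return List of class `pol_components`: `s_parallel`, `s_orthogonal`
#'   (spectrum tibbles, masked points NA), `frame`, and `mask`.
#' @export
decompose <- function(s_iso, r, beta_deg) {
  .check_same_axis(s_iso, r, "spectrum and anisotropy trace")
  frame <- decomposition_frame(beta_deg)
  mask <- if ("mask" %in% names(r)) r$mask else rep(TRUE, nrow(r))
  denom <- frame$r_parallel - frame$r_orthogonal
  s_par <- rep(NA_real_, nrow(s_iso))
  s_par[mask] <- s_iso$value[mask] * (r$r[mask] - frame$r_orthogonal) / denom
  s_ort <- s_iso$value - s_par
  dom <- attr(s_iso, "domain") %||% "absorbance"
  structure(
    list(
      s_parallel = spectrum_tbl(s_iso$wavenumber, replace(s_par, !mask, 0), domain = dom) |>
        (\(s) { s$value[!mask] <- NA_real_; s })(),
      s_orthogonal = spectrum_tbl(s_iso$wavenumber, replace(s_ort, !mask, 0), domain = dom) |>
        (\(s) { s$value[!mask] <- NA_real_; s })(),
      frame = frame,
      mask = mask
    ),
    class = "pol_components"
  )
}

#' Find the frame angle that suppresses a band from one component
#'
#' Scans a grid of beta values and returns the one minimising the integrated
#' magnitude of the orthogonal component over a wavenumber window (the
#' suppression objective). For a single species at angle delta to the
#' reference this recovers beta = delta exactly; applied to the window around
#' a band one wants removed from `s_orthogonal`, it returns the frame in
#' which that band lives purely in `s_parallel`. Ties break toward smaller
#' beta.
#'
#' @inheritParams decompose
#' @param window Numeric length-2 wavenumber window (cm^-1) over which the
#'   orthogonal component is integrated.
#' @param beta_grid Candidate beta values, degrees, subset of `[0, 45)`.
#' @return List: `beta_star`, `objective` (tibble beta vs integrated
#'   magnitude), `window`.
#' @export
optimize_beta <- function(s_iso, r, window,
                          beta_grid = seq(0, 44.9, by = 0.1)) {
  if (any(beta_grid < 0 | beta_grid >= 45)) {
    stop("beta grid must lie within [0, 45)", call. = FALSE)
  }
  if (length(window) != 2 || window[1] >= window[2]) {
    stop("window must be an increasing length-2 wavenumber range", call. = FALSE)
  }
  ax <- s_iso$wavenumber
  if (window[2] < min(ax) || window[1] > max(ax)) {
    stop("window lies outside the spectrum axis", call. = FALSE)
  }
  inwin <- ax >= window[1] & ax <= window[2]
  if (!any(inwin)) stop("window contains no axis points", call. = FALSE)
  obj <- vapply(beta_grid, function(b) {
    comp <- decompose(s_iso, r, b)
    v <- comp$s_orthogonal$value[inwin & comp$mask]
    sum(abs(v))
  }, numeric(1))
  best <- which(obj <= min(obj) + 0)  # exact ties -> smallest beta (grid ascending)
  list(
    beta_star = beta_grid[[min(best)]],
    objective = tibble::tibble(beta = beta_grid, objective = obj),
    window = window
  )
}

#' Recompute the anisotropy implied by a decomposition
#'
#' Round-trip check: given components and their frame anisotropies, the
#' mixture anisotropy is the intensity-weighted average
#' \eqn{r = (S_\parallel r_p + S_\perp r_o)/(S_\parallel + S_\perp)}.
#'
#' @param components A `pol_components` object from [decompose()].
#' @return Anisotropy tibble (`wavenumber`, `r`, `mask`).
#' @export
recompose_anisotropy <- function(components) {
  stopifnot(inherits(components, "pol_components"))
  f <- components$frame
  sp <- components$s_parallel$value
  so <- components$s_orthogonal$value
  tot <- sp + so
  r <- (sp * f$r_parallel + so * f$r_orthogonal) / tot
  tibble::tibble(wavenumber = components$s_parallel$wavenumber,
                 r = r, mask = components$mask & is.finite(r))
}
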