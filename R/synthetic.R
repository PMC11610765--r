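#' Add seeded white Gaussian noise
#'
#' Additive noise with standard deviation `fraction * max(|values|)`;
#' deterministic for a fixed seed, bitwise identity for `fraction = 0`.
#'
#' @param x Spectrum tibble or [ta_map()].
#' @param fraction Noise standard deviation as a fraction of the maximum
#'   absolute value, >= 0.
#' @param seed Integer seed; required when `fraction > 0`.
#' @return Same type as `x`.
#' @export
add_noise <- function(x, fraction, seed = NULL) {
  if (!is.finite(fraction) || fraction < 0) {
    stop("noise fraction must be >= 0", call. = FALSE)
  }
  if (fraction == 0) return(x)
  if (is.null(seed)) stop("a seed is required when noise fraction > 0", call. = FALSE)
  if (inherits(x, "ta_map")) {
    sd <- fraction * max(abs(x$dA))
    noise <- withr::with_seed(seed, stats::rnorm(length(x$dA), sd = sd))
    x$dA <- x$dA + matrix(noise, nrow = nrow(x$dA))
    x$meta$noise_sd <- sd
    x$meta$seed <- seed
    return(x)
  }
  stopifnot(is_spectrum(x))
  sd <- fraction * max(abs(x$value))
  x$value <- x$value + withr::with_seed(seed, stats::rnorm(nrow(x), sd = sd))
  x
}

#' Pump geometry for polarized TA generation
#'
#' @param species_tdm_angles Per-compartment angle (degrees) between the
#'   species' probed TDM and the decomposition reference axis.
#' @return A `pump_geometry` list.
#' @export
pump_geometry <- function(species_tdm_angles) {
  if (any(species_tdm_angles < 0 | species_tdm_angles > 180)) {
    stop("TDM angles must lie in [0, 180] degrees", call. = FALSE)
  }
  structure(list(species_tdm_angles = as.numeric(species_tdm_angles)),
            class = "pump_geometry")
}

#' Generate a synthetic TA map from known ground truth
#'
#' Concentrations follow the scheme's closed-form solution convolved with the
#' Gaussian IRF ([concentration_profiles()]); each species spectrum enters
#' with the standard photoselection factor for the requested probe
#' polarization, \eqn{f_\parallel = 1 + 0.8 P_2(\cos\delta)},
#' \eqn{f_\perp = 1 - 0.4 P_2(\cos\delta)}, \eqn{f_{MA} = 1}; the chirp shifts
#' the per-wavenumber time zero; optional white noise is seeded.
#'
#' @param scheme [kinetic_scheme()] (one compartment per species).
#' @param species List of species spectra (spectrum tibbles on a common
#'   axis), species-associated spectra in the delta-A sign convention
#'   (GSB/SE negative, ESA positive).
#' @param instrument [instrument_model()].
#' @param geometry [pump_geometry()] or NULL (required for parallel /
#'   perpendicular maps).
#' @param polarization "magic", "parallel" or "perpendicular".
#' @param delays Delays, fs.
#' @param noise_fraction White-noise sd as fraction of max |dA|.
#' @param seed Seed for the noise (required if `noise_fraction > 0`).
#' @param meta Extra metadata stored in the map.
#' @return A [ta_map()].
#' @export
gen_ta_map <- function(scheme, species, instrument = instrument_model(),
                       geometry = NULL,
                       polarization = c("magic", "parallel", "perpendicular"),
                       delays, noise_fraction = 0, seed = NULL, meta = list()) {
  polarization <- match.arg(polarization)
  stopifnot(inherits(scheme, "kinetic_scheme"))
  n <- length(scheme$lifetimes)
  if (length(species) != n) {
    stop("compartment count must equal species count", call. = FALSE)
  }
  axis <- species[[1]]$wavenumber
  for (s in species) .check_same_axis(species[[1]], s, "species spectra")
  if (polarization != "magic") {
    if (is.null(geometry)) {
      stop("parallel/perpendicular maps require a pump_geometry", call. = FALSE)
    }
    if (length(geometry$species_tdm_angles) != n) {
      stop("one TDM angle per species is required", call. = FALSE)
    }
    fpol <- .pol_factor(geometry$species_tdm_angles, polarization)
  } else {
    fpol <- rep(1, n)
  }
  sas <- vapply(seq_len(n), function(i) species[[i]]$value * fpol[[i]],
                numeric(length(axis)))
  t0w <- chirp_t0(instrument, axis)
  if (length(unique(t0w)) == 1) {
    C <- concentration_profiles(scheme, delays, instrument$irf_fwhm, t0w[[1]])
    dA <- C %*% t(sas)
  } else {
    dA <- matrix(0, length(delays), length(axis))
    for (j in seq_along(axis)) {
      Cj <- concentration_profiles(scheme, delays, instrument$irf_fwhm, t0w[[j]])
      dA[, j] <- Cj %*% sas[j, ]
    }
  }
  map <- ta_map(delays, axis, dA, polarization = polarization,
                meta = utils::modifyList(list(generator = "chladyn"), meta))
  if (noise_fraction > 0) map <- add_noise(map, noise_fraction, seed)
  map
}

#' Generate a steady-state excitation/emission + anisotropy data set
#'
#' Builds the excitation spectrum as the superposition of the band system,
#' the wavelength-resolved excitation anisotropy as the intensity-weighted
#' average of the per-band fundamental anisotropies
#' \eqn{r(\tilde\nu) = \sum_b A_b r_0(\delta_b) / \sum_b A_b}
#' (masked where total intensity < 1e-3 of the maximum), a mirrored emission
#' band, and the emission anisotropy implied by exciting at `lambda_exc_nm`.
#'
#' @param system [band_system()] with per-band TDM angles relative to the
#'   emissive transition.
#' @param axis Wavenumber grid, cm^-1.
#' @param noise_fraction White noise level on the spectra (the anisotropy is
#'   recomputed from the noisy polarized pair).
#' @param seed Seed, required for noisy output.
#' @param lambda_exc_nm Excitation wavelength for the emission-anisotropy
#'   trace, nm.
#' @param emission_stokes_cm1 Stokes shift applied to the mirrored emission
#'   band, cm^-1.
#' @return List: `excitation`, `emission` (spectrum tibbles), `r_exc`,
#'   `r_em` (anisotropy tibbles).
#' @export
gen_steady_state_set <- function(system, axis, noise_fraction = 0, seed = NULL,
                                 lambda_exc_nm = 660, emission_stokes_cm1 = 120) {
  stopifnot(inherits(system, "band_system"))
  comp <- system_components(system, axis)
  tot <- comp |>
    dplyr::summarise(value = sum(.data$value), .by = "wavenumber")
  r0 <- fundamental_anisotropy(vapply(system$bands, `[[`, numeric(1), "tdm_angle"))
  wsum <- comp |>
    dplyr::mutate(r0 = r0[match(.data$band, names(system$bands))]) |>
    dplyr::summarise(num = sum(.data$value * .data$r0), .by = "wavenumber")
  mask <- tot$value >= 1e-3 * max(tot$value)
  r_exc <- tibble::tibble(
    wavenumber = tot$wavenumber,
    r = ifelse(mask, wsum$num / tot$value, NA_real_),
    mask = mask
  )
  excitation <- spectrum_tbl(tot$wavenumber, tot$value, domain = "excitation")

  # emission: mirror of the first (emissive) band about its 0-0, small Stokes shift
  em_band <- system$bands[[1]]
  w <- fc_progression(em_band$huang_rhys, em_band$n_quanta)
  centers <- (em_band$e00 - emission_stokes_cm1) -
    (seq_len(em_band$n_quanta) - 1) * em_band$omega_vib
  ev <- rowSums(vapply(seq_along(w), function(i) {
    w[[i]] * exp(-(axis - centers[[i]])^2 / (2 * em_band$sigma^2))
  }, numeric(length(axis))))
  if (max(ev) > 0) ev <- ev / max(ev)
  emission <- spectrum_tbl(axis, ev, domain = "emission")

  # emission anisotropy: emission always from band 1; its value is the
  # intensity-weighted absorber anisotropy at the fixed excitation wavelength
  nu_exc <- wavelength_to_wavenumber(lambda_exc_nm)
  j <- which.min(abs(axis - nu_exc))
  r_at_exc <- r_exc$r[[j]]
  em_mask <- ev >= 1e-3 * max(ev)
  r_em <- tibble::tibble(wavenumber = axis,
                         r = ifelse(em_mask, r_at_exc, NA_real_),
                         mask = em_mask)

  if (noise_fraction > 0) {
    if (is.null(seed)) stop("a seed is required when noise fraction > 0", call. = FALSE)
    # noise the polarized pair consistently, then recompute r
    ipar <- spectrum_tbl(axis, excitation$value * (1 + 2 * r_exc$r * ifelse(mask, 1, 0)) / 3,
                         domain = "excitation")
    iperp <- spectrum_tbl(axis, excitation$value * (1 - r_exc$r * ifelse(mask, 1, 0)) / 3,
                          domain = "excitation")
    ipar <- add_noise(ipar, noise_fraction, seed)
    iperp <- add_noise(iperp, noise_fraction, seed + 1L)
    excitation <- spectrum_tbl(axis, ipar$value + 2 * iperp$value,
                               domain = "excitation")
    r_exc <- anisotropy_from_pair(ipar, iperp)
    emission <- add_noise(emission, noise_fraction, seed + 2L)
  }
  list(excitation = excitation, emission = emission, r_exc = r_exc, r_em = r_em)
}

#' Generate the polarized TA pair used for transient anisotropy analysis
#'
#' Convenience wrapper producing parallel, perpendicular and magic maps from
#' the same ground truth (same scheme, species, instrument, geometry). The
#' polarized pair always satisfies the magic-angle identity
#' (parallel + 2 perpendicular)/3 = magic before noise.
#'
#' @inheritParams gen_ta_map
#' @param seed Seed; the three maps use `seed`, `seed + 1`, `seed + 2`.
#' @return List of [ta_map()]s: `parallel`, `perpendicular`, `magic`.
#' @export
gen_taa_set <- function(scheme, species, instrument, geometry, delays,
                        noise_fraction = 0, seed = NULL, meta = list()) {
  gen <- function(pol, s) {
    gen_ta_map(scheme, species, instrument, geometry, pol, delays,
               noise_fraction = noise_fraction, seed = s, meta = meta)
  }
  list(parallel = gen("parallel", seed),
       perpendicular = gen("perpendicular", if (is.null(seed)) NULL else seed + 1L),
       magic = gen("magic", if (is.null(seed)) NULL else seed + 2L))
}
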