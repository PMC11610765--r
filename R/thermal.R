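#' Biphasic heat-flow (effective temperature) model
#'
#' After photoexcitation the excess vibrational energy
#' \eqn{E_{dep} = \max(E_{photon} - E_{00}, 0)} thermalises within the solute
#' on the IVR timescale and flows to the solvation shell / bulk on the
#' vibrational-cooling timescale, described by an effective molecular
#' temperature \eqn{T_m(t)}.
#'
#' @param e_photon Excitation photon energy, cm^-1.
#' @param e_00 0-0 energy of the emitting state, cm^-1.
#' @param tau_ivr IVR (rise) timescale, ps.
#' @param tau_vc Vibrational-cooling (decay) timescale, ps; must exceed
#'   `tau_ivr`.
#' @param t_bath Bath temperature, K.
#' @param heat_capacity Effective molecular heat capacity, cm^-1/K.
#' @return A `thermal_config` list.
#' @export
thermal_config <- function(e_photon, e_00 = 14925, tau_ivr = 1, tau_vc = 8,
                           t_bath = 295, heat_capacity = 83.3) {
  if (!(tau_vc > tau_ivr) || tau_ivr <= 0) {
    stop("need tau_vc > tau_ivr > 0 (use distinct timescales; the confluent limit is not implemented)",
         call. = FALSE)
  }
  if (heat_capacity <= 0) stop("heat_capacity must be > 0", call. = FALSE)
  structure(list(e_photon = e_photon, e_00 = e_00, tau_ivr = tau_ivr,
                 tau_vc = tau_vc, t_bath = t_bath,
                 heat_capacity = heat_capacity),
            class = "thermal_config")
}

#' Load solvent/excitation thermal configs from YAML
#'
#' @param name Fixture entry, `"<solvent>_<band>"` e.g. "acetone_B".
#' @param path YAML file with per-entry fields.
#' @return A [thermal_config()].
#' @export
load_thermal_config <- function(name, path = chladyn_fixture("thermal_fixtures.yaml")) {
  cfg <- yaml::read_yaml(path)
  e <- cfg[[name]]
  if (is.null(e)) stop("no thermal fixture named ", name, call. = FALSE)
  thermal_config(e_photon = e$e_photon, e_00 = e$e_00 %||% 14925,
                 tau_ivr = e$tau_ivr, tau_vc = e$tau_vc,
                 t_bath = e$t_bath %||% 295,
                 heat_capacity = e$heat_capacity %||% 83.3)
}

#' Deposited excess vibrational energy
#'
#' @param config A [thermal_config()].
#' @return \eqn{E_{dep} = \max(E_{photon} - E_{00}, 0)} in cm^-1.
#' @export
deposited_energy <- function(config) {
  stopifnot(inherits(config, "thermal_config"))
  max(config$e_photon - config$e_00, 0)
}

#' Peak time of the biphasic temperature transient
#'
#' Closed form \eqn{t^* = \tau_i \tau_v \ln(\tau_v/\tau_i) / (\tau_v - \tau_i)}.
#'
#' @param tau_ivr,tau_vc Timescales, ps.
#' @return Peak time, ps.
#' @export
tm_peak_time <- function(tau_ivr, tau_vc) {
  tau_ivr * tau_vc * log(tau_vc / tau_ivr) / (tau_vc - tau_ivr)
}

#' Effective molecular temperature trace
#'
#' \deqn{T_m(t) = T_{bath} + \frac{E_{dep}}{C}\,k\,
#'       (e^{-t/\tau_{VC}} - e^{-t/\tau_{IVR}})}
#' with k normalising the biphasic bracket to unit peak, so the peak
#' temperature rise is exactly \eqn{E_{dep}/C}. Rise is governed by
#' \eqn{\tau_{IVR}}, the cooling tail by \eqn{\tau_{VC}}.
#'
#' @param config A [thermal_config()].
#' @param times Times, ps (>= 0).
#' @return Tibble `time`, `T_m` (K).
#' @export
simulate_Tm <- function(config, times) {
  stopifnot(inherits(config, "thermal_config"))
  e_dep <- deposited_energy(config)
  ti <- config$tau_ivr; tv <- config$tau_vc
  tstar <- tm_peak_time(ti, tv)
  peak <- exp(-tstar / tv) - exp(-tstar / ti)
  bracket <- exp(-times / tv) - exp(-times / ti)
  tibble::tibble(
    time = times,
    T_m = config$t_bath + (e_dep / config$heat_capacity) * bracket / peak
  )
}

#' Two-compartment energy flow underlying the temperature model
#'
#' Bookkeeping form: unthermalised energy decays into the thermalised pool at
#' rate 1/tau_IVR; the pool releases heat to the bath at rate 1/tau_VC. The
#' time-integrated heat delivered to the bath equals the deposited energy.
#'
#' @param config A [thermal_config()].
#' @param times Times, ps.
#' @return Tibble `time`, `E_hot`, `E_thermal`, `heat_rate` (cm^-1 and
#'   cm^-1/ps).
#' @export
energy_flow <- function(config, times) {
  stopifnot(inherits(config, "thermal_config"))
  e_dep <- deposited_energy(config)
  ti <- config$tau_ivr; tv <- config$tau_vc
  e_hot <- e_dep * exp(-times / ti)
  e_th <- e_dep * (tv / (tv - ti)) * (exp(-times / tv) - exp(-times / ti))
  tibble::tibble(time = times, E_hot = e_hot, E_thermal = e_th,
                 heat_rate = e_th / tv)
}

#' Temperature-dependent band width
#'
#' Harmonic-bath-motivated square-root broadening:
#' \eqn{\sigma(T) = \sqrt{\sigma_0^2 + c^2 (T - T_{bath})}}, monotone in T.
#'
#' @param temperature Temperature(s), K (>= 0).
#' @param band A [vibronic_band()] providing the zero-excess width sigma0.
#' @param coupling_sd Broadening coefficient c, cm^-1 per sqrt(K).
#' @param t_bath Bath temperature, K.
#' @return Broadened sigma, cm^-1.
#' @export
temp_to_linewidth <- function(temperature, band, coupling_sd = 10, t_bath = 295) {
  if (any(temperature < 0)) stop("temperature must be >= 0 K", call. = FALSE)
  sqrt(band$sigma^2 + coupling_sd^2 * pmax(temperature - t_bath, 0))
}

#' Predicted band evolution under heating and cooling
#'
#' Re-renders a vibronic band at each delay with the width implied by the
#' effective temperature at that time; amplitudes are rescaled so the
#' integrated band area is conserved (broadening redistributes, it does not
#' create, oscillator strength).
#'
#' @param config A [thermal_config()].
#' @param band [vibronic_band()] being heated (typically the lowest band).
#' @param delays Delays, ps.
#' @param axis Wavenumber grid, cm^-1.
#' @param coupling_sd Broadening coefficient, cm^-1 per sqrt(K).
#' @return Tibble `delay`, `wavenumber`, `value`, `sigma`, `T_m`.
#' @export
predict_band_evolution <- function(config, band, delays, axis,
                                   coupling_sd = 10) {
  tm <- simulate_Tm(config, delays)
  ref <- make_vibronic_band(band, axis)
  area0 <- sum(ref$value) * mean(diff(axis))
  purrr::map2_dfr(delays, seq_along(delays), function(d, i) {
    sig <- temp_to_linewidth(tm$T_m[[i]], band, coupling_sd, config$t_bath)
    b <- vibronic_band(band$e00, band$omega_vib, band$huang_rhys, sig,
                       band$tdm_angle, band$amplitude, band$n_quanta)
    s <- make_vibronic_band(b, axis)
    area <- sum(s$value) * mean(diff(axis))
    tibble::tibble(delay = d, wavenumber = axis,
                   value = s$value * area0 / area,
                   sigma = sig, T_m = tm$T_m[[i]])
  })
}
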