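# shared helpers: small spectra and model configs built in code

gauss_spectrum <- function(axis, center, sigma, amplitude = 1, domain = "absorbance") {
  spectrum_tbl(axis, amplitude * exp(-(axis - center)^2 / (2 * sigma^2)),
               domain = domain)
}

# two band systems at angles (delta1, delta2) to the reference, spectrally
# separated so each dominates its own window; the exact anisotropy is the
# intensity-weighted average of the fundamental anisotropies
two_system_mixture <- function(delta1, delta2, axis = seq(13000, 19000, by = 20)) {
  s1 <- gauss_spectrum(axis, 15000, 200)
  s2 <- gauss_spectrum(axis, 17000, 200, amplitude = 0.6)
  iso <- spectrum_tbl(axis, s1$value + s2$value)
  r1 <- fundamental_anisotropy(delta1)
  r2 <- fundamental_anisotropy(delta2)
  tot <- s1$value + s2$value
  mask <- tot >= 1e-3 * max(tot)
  r <- tibble::tibble(wavenumber = axis,
                      r = ifelse(mask, (s1$value * r1 + s2$value * r2) / tot, NA_real_),
                      mask = mask)
  list(iso = iso, r = r)
}

# minimal 5-state config for propagator oracles: a near-degenerate two-level
# block (Qy, Qx) with constant coupling, everything else parked far away and
# uncoupled
write_two_level_config <- function(value = 0.10, gap = 0,
                                   grid_points = c(32, 32), dt = 0.05) {
  path <- tempfile(fileext = ".yaml")
  cfg <- list(
    fixture_version = 1,
    mode_freqs = c(1489, 1639),
    grid = list(points = as.integer(grid_points), qmax = 6),
    state_energies = list(S0 = 0, Qy = 2.0, Qx = 2.0 + gap, Bx = 30.0, By = 31.0),
    couplings = list(list(states = c("Qx", "Qy"), value = value,
                          shape = list(type = "constant"))),
    dt = dt, t_final = 50, record_every = 2
  )
  yaml::write_yaml(cfg, path)
  path
}

write_pulse_config <- function(dipole = 14.12, peak_field = 0.0026,
                               fwhm = 20, omega0 = 3.60) {
  path <- tempfile(fileext = ".yaml")
  cfg <- list(
    fixture_version = 1,
    mode_freqs = c(1489, 1639),
    grid = list(points = c(32L, 32L), qmax = 6),
    state_energies = list(S0 = 0, Qy = 20.0, Qx = 21.0, Bx = 22.0, By = omega0),
    couplings = list(list(states = c("Qx", "Qy"), value = 0,
                          shape = list(type = "constant"))),
    dt = 0.05, t_final = 120, record_every = 10,
    pulse = list(peak_field = peak_field, fwhm = fwhm, omega0 = omega0,
                 dipoles = list("S0-By" = dipole))
  )
  yaml::write_yaml(cfg, path)
  path
}
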