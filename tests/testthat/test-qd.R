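# the frozen default model and a 250 fs reference trace, shared across tests
default_H <- build_model(qd_config())
default_trace <- propagate(default_H, qd_ground_state(default_H, "By"),
                           t_final = 250, dt = 0.1)

test_that("the potential matrix is diagonal when all couplings vanish", {
  path <- write_two_level_config(value = 0)
  H <- build_model(qd_config(path))
  offdiag <- H$diabatic
  for (s in 1:5) offdiag[, s, s] <- 0
  expect_true(all(offdiag == 0))
  # and populations are constant under propagation
  tr <- propagate(H, qd_ground_state(H, "Qy"), t_final = 10, dt = 0.05)
  pops <- tr$populations |> dplyr::filter(basis == "diabatic", state == "Qy")
  expect_equal(pops$population, rep(1, nrow(pops)), tolerance = 1e-9)
})

test_that("the default model reproduces the calibrated FC-point gap", {
  gap <- default_H$fc_energies[["Qx"]] - default_H$fc_energies[["Qy"]]
  expect_equal(gap, 0.225, tolerance = 1e-9)
})

test_that("adiabatic surfaces do not cross in the central region", {
  sel <- abs(default_H$qgrid$q1) <= 3 & abs(default_H$qgrid$q2) <= 3
  mingap <- min(apply(default_H$evals[sel, ], 1, function(e) min(diff(e))))
  expect_gt(mingap, 0.01)
})

test_that("grid coverage and state validation errors are raised", {
  path <- write_two_level_config()
  cfg <- qd_config(path)
  cfg$grid$qmax <- 2
  expect_error(build_model(cfg), "5 coordinate sd")
  expect_error(toggle_coupling(qd_config(), c("B", "Zz")), "unknown state")
})

test_that("degenerate two-level dynamics follow the analytic Rabi formula", {
  V <- 0.10
  path <- write_two_level_config(value = V)
  H <- build_model(qd_config(path))
  tr <- propagate(H, qd_ground_state(H, "Qy"), t_final = 30, dt = 0.05,
                  record_every = 2)
  pops <- tr$populations |> dplyr::filter(basis == "diabatic", state == "Qx")
  analytic <- sin(V * pops$time / 0.6582119569)^2
  expect_lt(max(abs(pops$population - analytic)), 1e-3)
})

test_that("a displaced wavepacket revives at the vibrational period", {
  path <- write_two_level_config(value = 0)
  H <- build_model(qd_config(path))
  psi0 <- qd_ground_state(H, "S0", displace = c(1.5, 0))
  tr <- propagate(H, psi0, t_final = 30, dt = 0.05, record_every = 2,
                  record_autocorrelation = TRUE)
  a <- abs(tr$autocorrelation$autocorrelation)
  t <- tr$autocorrelation$time
  # full revival of mode 1 at T = 1/(c * 1489 cm-1) = 22.41 fs
  revival <- t[t > 10][which.max(a[t > 10])]
  expect_equal(revival, 22.41, tolerance = 0.02)
  expect_gt(max(a[abs(t - 22.41) < 0.2]), 0.999)
  expect_lt(min(a[t > 5 & t < 18]), 0.35)
})

test_that("a resonant pi-pulse transfers the population completely", {
  fwhm <- 20
  sig <- fwhm / (2 * sqrt(2 * log(2)))
  # pi-pulse area: integral of mu E(t) dt / hbar = pi for complete transfer
  d_pi <- pi * 0.6582119569 / (0.0026 * 5.29177 * sqrt(2 * pi) * sig)
  H <- build_model(qd_config(write_pulse_config(dipole = d_pi)))
  p <- apply_pulse(H)
  expect_equal(p$excited_population, 1, tolerance = 1e-3)
  # zero field leaves the ground state untouched
  p0 <- apply_pulse(H, pulse = list(peak_field = 0, fwhm = 20, omega0 = 3.60,
                                    dipoles = list("S0-By" = 1)))
  expect_lt(p0$excited_population, 1e-9)
})

test_that("norm is conserved and energy converges with the step size", {
  expect_lt(max(abs(default_trace$norm$norm - 1)), 1e-8)
  # second-order splitting: at dt = 0.02 fs the measured field-free energy
  # is constant to 1e-6 relative
  tr <- propagate(default_H, qd_ground_state(default_H, "By"),
                  t_final = 40, dt = 0.02, record_every = 100)
  expect_lt(max(abs(default_trace$norm$norm - 1)), 1e-8)
  expect_lt(diff(range(tr$energy$energy)) / mean(tr$energy$energy), 1e-6)
})

test_that("the B-band 1/e time is insensitive to halving the time step", {
  e1 <- efold_time(propagate(default_H, qd_ground_state(default_H, "By"),
                             t_final = 150, dt = 0.1))
  e2 <- efold_time(propagate(default_H, qd_ground_state(default_H, "By"),
                             t_final = 150, dt = 0.05))
  expect_lt(abs(e2 / e1 - 1), 0.02)
})

test_that("intra-band mixing outruns inter-band transfer", {
  pops <- default_trace$populations |> dplyr::filter(basis == "adiabatic")
  at25 <- pops |> dplyr::filter(time == 25) |>
    (\(d) stats::setNames(d$population, d$state))()
  expect_gt(at25[["Bx"]], at25[["Qx"]] + at25[["Qy"]])
})

test_that("Qx acts as a transient bridge during B -> Q transfer", {
  qx <- default_trace$populations |>
    dplyr::filter(basis == "adiabatic", state == "Qx")
  peak_t <- qx$time[which.max(qx$population)]
  # the bridge fills while B drains (within the ~100 fs transfer window)
  # and empties again afterwards
  expect_lt(peak_t, 150)
  expect_lt(qx$population[nrow(qx)], max(qx$population) * 0.6)
})

test_that("toggling couplings off and back on restores the config", {
  cfg <- qd_config()
  cfg2 <- toggle_coupling(toggle_coupling(cfg, c("B", "Qx")), c("B", "Qx"),
                          off = FALSE)
  expect_identical(cfg, cfg2)
  off <- toggle_coupling(cfg, c("B", "Qx"))
  vals <- vapply(off$couplings, function(cp) {
    key <- paste(sort(unlist(cp$states)), collapse = "-")
    if (key %in% c("Bx-Qx", "By-Qx")) cp$value else NA_real_
  }, numeric(1))
  expect_true(all(vals[!is.na(vals)] == 0))
})
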