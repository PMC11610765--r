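test_that("deposited energy is the non-negative photon excess", {
  cfg <- thermal_config(e_photon = 14925, e_00 = 14925)
  expect_equal(deposited_energy(cfg), 0)
  cfg2 <- thermal_config(e_photon = 23256, e_00 = 14925)
  expect_equal(deposited_energy(cfg2), 8331)
  b <- load_thermal_config("acetone_B")
  q <- load_thermal_config("acetone_Q")
  expect_gt(deposited_energy(b), deposited_energy(q))
})

test_that("temperature transient peaks at the closed-form time", {
  expect_equal(tm_peak_time(1, 8), log(8) * 8 / 7, tolerance = 1e-12)
  cfg <- load_thermal_config("acetone_B")
  t <- seq(0, 60, by = 1e-3)
  tm <- simulate_Tm(cfg, t)
  expect_equal(tm$time[which.max(tm$T_m)], tm_peak_time(1, 8), tolerance = 2e-3)
  # monotone rise then monotone decay
  ipk <- which.max(tm$T_m)
  expect_true(all(diff(tm$T_m[1:ipk]) >= 0))
  expect_true(all(diff(tm$T_m[ipk:length(t)]) <= 0))
  # T_m >= bath, relaxes to bath
  expect_true(all(tm$T_m >= cfg$t_bath - 1e-9))
  expect_equal(tm$T_m[length(t)], cfg$t_bath, tolerance = 0.1)
})

test_that("zero excess energy leaves the bath temperature untouched", {
  cfg <- thermal_config(e_photon = 14925, e_00 = 14925)
  tm <- simulate_Tm(cfg, seq(0, 20, by = 0.1))
  expect_equal(tm$T_m, rep(cfg$t_bath, nrow(tm)))
})

test_that("peak heating is ordered B > Q with near-identical tails", {
  t <- seq(0, 60, by = 0.01)
  tb <- simulate_Tm(load_thermal_config("acetone_B"), t)
  tq <- simulate_Tm(load_thermal_config("acetone_Q"), t)
  expect_gt(max(tb$T_m), max(tq$T_m))
  # same timescales: normalised transients coincide
  nb <- (tb$T_m - 295) / max(tb$T_m - 295)
  nq <- (tq$T_m - 295) / max(tq$T_m - 295)
  expect_equal(nb, nq, tolerance = 1e-9)
})

test_that("the cooling tail decays with 1/tau_VC", {
  cfg <- load_thermal_config("acetone_B")
  t <- seq(4 * cfg$tau_vc, 8 * cfg$tau_vc, by = 0.05)
  tm <- simulate_Tm(cfg, t)
  slope <- stats::coef(stats::lm(log(tm$T_m - cfg$t_bath) ~ t))[[2]]
  expect_equal(slope, -1 / cfg$tau_vc, tolerance = 0.01 / cfg$tau_vc)
})

test_that("two-compartment flow delivers exactly the deposited energy", {
  cfg <- load_thermal_config("acetone_B")
  t <- seq(0, 400, by = 0.005)
  fl <- energy_flow(cfg, t)
  delivered <- sum((fl$heat_rate[-1] + fl$heat_rate[-nrow(fl)]) / 2 * diff(t))
  expect_equal(delivered, deposited_energy(cfg), tolerance = 1e-4 * deposited_energy(cfg))
  # pools are non-negative and the hot pool decays with tau_IVR
  expect_true(all(fl$E_hot >= 0) && all(fl$E_thermal >= -1e-9))
})

test_that("solvent fixtures order the cooling tails by tau_VC", {
  t <- seq(25, 60, by = 0.1)
  tails <- vapply(c("benzonitrile_B", "acetone_B", "ethanol_B"), function(nm) {
    cfg <- load_thermal_config(nm)
    tm <- simulate_Tm(cfg, t)
    stats::coef(stats::lm(log(tm$T_m - cfg$t_bath) ~ t))[[2]]
  }, numeric(1))
  # slower cooling (larger tau_VC) gives a shallower slope
  expect_true(tails[["benzonitrile_B"]] < tails[["acetone_B"]])
  expect_true(tails[["acetone_B"]] < tails[["ethanol_B"]])
})

test_that("thermal broadening is monotone and starts at sigma0", {
  band <- vibronic_band(14925, 1250, 0.3, 170)
  expect_equal(temp_to_linewidth(295, band), 170)
  temps <- seq(295, 500, by = 5)
  w <- temp_to_linewidth(temps, band)
  expect_true(all(diff(w) > 0))
  expect_error(temp_to_linewidth(-5, band), ">= 0")
  expect_error(thermal_config(23256, tau_ivr = 2, tau_vc = 1), "tau_vc > tau_ivr")
})

test_that("band evolution is biphasic in width and conserves area", {
  cfg <- load_thermal_config("acetone_B")
  band <- vibronic_band(14925, 1250, 0.3, 170)
  axis <- seq(12000, 18500, by = 10)
  delays <- c(0.2, 1, tm_peak_time(1, 8), 20)
  ev <- predict_band_evolution(cfg, band, delays, axis)
  w <- ev |> dplyr::distinct(.data$delay, .data$sigma)
  expect_gt(w$sigma[w$delay == 1], w$sigma[w$delay == 0.2])
  expect_gt(w$sigma[w$delay == 1], w$sigma[w$delay == 20])
  expect_equal(max(w$sigma), w$sigma[3])  # widest at the peak time
  areas <- ev |>
    dplyr::summarise(a = sum(.data$value) * 10, .by = "delay")
  expect_equal(areas$a, rep(areas$a[1], 4), tolerance = 1e-10)

  # no excess energy: identical spectra at all delays
  cfg0 <- thermal_config(14925, 14925)
  ev0 <- predict_band_evolution(cfg0, band, c(1, 10), axis)
  expect_equal(ev0$value[ev0$delay == 1], ev0$value[ev0$delay == 10])
})
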