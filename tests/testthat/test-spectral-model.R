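test_that("Franck-Condon progressions are truncated Poisson weights", {
  expect_equal(fc_progression(0, 3), c(1, 0, 0))
  w <- fc_progression(0.3, 2)
  expect_equal(w[2] / w[1], 0.3)
  expect_equal(sum(fc_progression(1, 50)), 1, tolerance = 1e-12)
  # monotone decrease for S < 1
  for (s in c(0.2, 0.5, 0.9)) {
    expect_true(all(diff(fc_progression(s, 6)) < 0))
  }
  expect_error(fc_progression(-0.1, 3), "non-negative")
  expect_error(fc_progression(0.5, 0), "positive integer")
})

test_that("vibronic bands render as weighted Gaussian progressions", {
  axis <- seq(13500, 18500, by = 5)
  b <- vibronic_band(e00 = 14925, omega_vib = 1250, huang_rhys = 0,
                     sigma = 170, amplitude = 2)
  s <- make_vibronic_band(b, axis)
  # S = 0: a single Gaussian peaking at e00 with the requested amplitude
  expect_equal(s$wavenumber[which.max(s$value)], 14925, tolerance = 5)
  expect_equal(max(s$value), 2, tolerance = 1e-6)
  expect_equal(s$value, 2 * exp(-(axis - 14925)^2 / (2 * 170^2)), tolerance = 1e-9)

  # default-like Qy parameters still peak at the 0-0 origin
  b2 <- vibronic_band(14925, 1250, 0.30, 170)
  s2 <- make_vibronic_band(b2, axis)
  expect_lte(abs(s2$wavenumber[which.max(s2$value)] - 14925), 5 / 2 + 1e-9)

  # zero amplitude gives a zero spectrum
  b0 <- vibronic_band(14925, 1250, 0.3, 170, amplitude = 0)
  expect_true(all(make_vibronic_band(b0, axis)$value == 0))
})

test_that("band rendering is linear in amplitude and shift-equivariant", {
  axis <- seq(12000, 20000, by = 10)
  mk <- function(amp, e00) {
    make_vibronic_band(vibronic_band(e00, 1200, 0.4, 200, amplitude = amp), axis)
  }
  expect_equal(mk(3, 15000)$value, 3 * mk(1, 15000)$value, tolerance = 1e-12)
  shift <- 500
  s1 <- mk(1, 15000); s2 <- mk(1, 15000 + shift)
  i <- axis >= 13000 & axis <= 18000
  interp <- stats::approx(axis, s2$value, xout = axis[i] + shift)$y
  expect_equal(s1$value[i], interp, tolerance = 1e-6)
})

test_that("wavelength/wavenumber conversion is the 1e7/x involution", {
  expect_equal(wavelength_to_wavenumber(625), 16000)
  expect_equal(wavelength_to_wavenumber(580), 1e7 / 580, tolerance = 1e-12)
  expect_equal(wavenumber_to_wavelength(10000), 1000)
  x <- c(400, 550, 700.3)
  expect_equal(wavenumber_to_wavelength(wavelength_to_wavenumber(x)), x)
  expect_error(wavelength_to_wavenumber(0), "positive")
  expect_error(wavenumber_to_wavelength(-5), "positive")
})

test_that("spectrum tibbles enforce their invariants", {
  expect_error(spectrum_tbl(c(1, 2), c(1, 2, 3)), "equal length")
  expect_error(spectrum_tbl(c(2, 1), c(1, 2)), "ascending")
  expect_error(spectrum_tbl(c(1, 2), c(1, NA)), "NA")
  s <- spectrum_tbl(c(1, 2), c(3, 4), domain = "emission")
  expect_s3_class(s, "tbl_df")
  expect_identical(attr(s, "domain"), "emission")
})

test_that("band systems superpose and expose per-band components", {
  sys <- load_band_system()
  axis <- seq(13800, 25400, by = 50)
  tot <- system_spectrum(sys, axis)
  comp <- system_components(sys, axis)
  by_band <- tidyr::pivot_wider(comp, id_cols = "wavenumber",
                                names_from = "band", values_from = "value")
  expect_equal(rowSums(by_band[, -1]), tot$value, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_setequal(unique(comp$band), c("Qy", "Qx", "Bx", "By"))
  expect_error(band_system(), "non-empty")
})
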