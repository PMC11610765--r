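test_that("fundamental anisotropy follows 0.4 P2(cos delta)", {
  expect_equal(fundamental_anisotropy(0), 0.4)
  expect_equal(fundamental_anisotropy(90), -0.2)
  expect_equal(fundamental_anisotropy(54.7356), 0, tolerance = 1e-6)
  expect_equal(fundamental_anisotropy(73), -0.148711, tolerance = 1e-5)
  expect_error(fundamental_anisotropy(-1), "0, 180")
})

test_that("anisotropy and magic-angle signals from polarized pairs", {
  ax <- c(100, 200, 300)
  par <- spectrum_tbl(ax, c(1.8, 1, 1))
  perp <- spectrum_tbl(ax, c(0.6, 1, 2))
  r <- anisotropy_from_pair(par, perp)
  expect_equal(r$r, c(0.4, 0, -0.2))
  expect_equal(magic_from_pair(spectrum_tbl(ax, c(3, 1, 0)),
                               spectrum_tbl(ax, c(0, 1, 0)))$value,
               c(1, 1, 0))
  expect_error(anisotropy_from_pair(par, spectrum_tbl(ax + 1, c(1, 1, 1))),
               "different wavenumber axes")
})

test_that("low-intensity points are masked, not interpolated", {
  ax <- seq(1, 100)
  v <- exp(-(ax - 50)^2 / 50)
  par <- spectrum_tbl(ax, v * 1.8)
  perp <- spectrum_tbl(ax, v * 0.6)
  r <- anisotropy_from_pair(par, perp)
  expect_true(any(!r$mask))
  expect_true(all(is.na(r$r[!r$mask])))
  expect_equal(r$r[r$mask], rep(0.4, sum(r$mask)))
})

test_that("decomposition is exactly additive and invertible", {
  mix <- two_system_mixture(17, 90)
  comp <- decompose(mix$iso, mix$r, 17)
  ok <- comp$mask
  # additivity: components reconstruct the isotropic input to rounding
  expect_equal(comp$s_parallel$value[ok] + comp$s_orthogonal$value[ok],
               mix$iso$value[ok], tolerance = 1e-14)
  # round trip through the frame anisotropies reproduces r
  back <- recompose_anisotropy(comp)
  expect_lt(max(abs(back$r[ok] - mix$r$r[ok])), 1e-10)
})

test_that("component anisotropy r_p maps a pure species into S_parallel", {
  ax <- seq(14000, 16000, by = 10)
  iso <- gauss_spectrum(ax, 15000, 150)
  frame <- decomposition_frame(17)
  r <- tibble::tibble(wavenumber = ax, r = rep(frame$r_parallel, length(ax)),
                      mask = TRUE)
  comp <- decompose(iso, r, 17)
  expect_equal(comp$s_orthogonal$value, rep(0, length(ax)), tolerance = 1e-12)
  expect_equal(comp$s_parallel$value, iso$value, tolerance = 1e-12)
})

test_that("flat anisotropy between the frame values splits the intensity", {
  ax <- c(1000, 2000)
  iso <- spectrum_tbl(ax, c(1, 1))
  r <- tibble::tibble(wavenumber = ax, r = c(0.1, 0.1), mask = TRUE)
  comp <- decompose(iso, r, 0)
  expect_equal(comp$s_parallel$value, c(0.5, 0.5))
  expect_equal(comp$s_orthogonal$value, c(0.5, 0.5))
  expect_error(decompose(iso, r, 45), "45")
})

test_that("beta scan recovers the angle of a single component exactly", {
  ax <- seq(14500, 15500, by = 10)
  iso <- gauss_spectrum(ax, 15000, 150)
  for (delta in c(5, 17, 32, 40)) {
    r <- tibble::tibble(wavenumber = ax,
                        r = rep(fundamental_anisotropy(delta), length(ax)),
                        mask = TRUE)
    ob <- optimize_beta(iso, r, window = c(14800, 15200))
    expect_equal(ob$beta_star, delta, tolerance = 0.051)
  }
})

test_that("beta scan recovers 90 - theta for two-system mixtures", {
  for (theta in c(60, 73, 80, 90)) {
    mix <- two_system_mixture(90 - theta, 90)
    ob <- optimize_beta(mix$iso, mix$r, window = c(14600, 15400))
    expect_equal(ob$beta_star, 90 - theta, tolerance = 0.051)
  }
})

test_that("beta scan rejects bad windows and grids", {
  mix <- two_system_mixture(17, 90)
  expect_error(optimize_beta(mix$iso, mix$r, window = c(30000, 31000)),
               "outside")
  expect_error(optimize_beta(mix$iso, mix$r, window = c(14600, 15400),
                             beta_grid = c(10, 46)), "45")
})

test_that("steady-state fixture decomposes at beta = 17 into clean components", {
  ss <- steady_state_fixture()
  i <- which.min(abs(ss$excitation$wavenumber - 14925))
  expect_equal(ss$r_exc$r[i], 0.349, tolerance = 0.01)
  comp <- decompose(ss$excitation, ss$r_exc, 17)
  expect_lt(abs(comp$s_orthogonal$value[i]) / ss$excitation$value[i], 0.01)
  ob <- optimize_beta(ss$excitation, ss$r_exc, window = c(14600, 15100))
  expect_equal(ob$beta_star, 17, tolerance = 0.5)
  expect_equal(90 - ob$beta_star, 73, tolerance = 0.5)
})

test_that("bi-gaussian fits recover exact and noisy band pairs", {
  ax <- seq(15000, 18200, by = 25)
  truth <- 0.9 * exp(-(ax - 16000)^2 / (2 * 280^2)) +
    0.6 * exp(-(ax - 17100)^2 / (2 * 320^2))
  fit <- fit_bigaussian(spectrum_tbl(ax, truth), init_centers = c(15900, 17200))
  expect_equal(fit$centers, c(16000, 17100), tolerance = 1e-4)
  expect_equal(fit$spacing, 1100, tolerance = 1e-3)
  expect_false(fit$degenerate)

  noisy <- truth + withr::with_seed(7, stats::rnorm(length(ax), sd = 0.02 * max(truth)))
  fitn <- fit_bigaussian(spectrum_tbl(ax, noisy), init_centers = c(15900, 17200))
  expect_equal(fitn$spacing, 1100, tolerance = 25)
})

test_that("bi-gaussian degeneracy is flagged on a single-band input", {
  ax <- seq(15000, 18000, by = 25)
  single <- spectrum_tbl(ax, exp(-(ax - 16500)^2 / (2 * 300^2)))
  fit <- fit_bigaussian(single, init_centers = c(16300, 16700))
  expect_true(fit$degenerate)
  expect_error(fit_bigaussian(single[1:5, ], init_centers = c(16300, 16700)),
               "10 points")
})
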