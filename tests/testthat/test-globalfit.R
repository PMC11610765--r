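make_map <- function(taus, eas, delays, ax, irf = 30, noise = 0, seed = NULL,
                     chirp = 0) {
  species <- lapply(seq_len(nrow(eas)), function(i) spectrum_tbl(ax, eas[i, ],
                                                                 domain = "delta_A"))
  gen_ta_map(kinetic_scheme(taus, "sequential"), species,
             instrument_model(irf, 0, chirp), polarization = "magic",
             delays = delays, noise_fraction = noise, seed = seed)
}

test_that("noiseless single-component self-fit recovers tau to 1e-6", {
  ax <- seq(14000, 16000, by = 100)
  delays <- seq(-100, 6000, by = 100)
  map <- make_map(1000, matrix(exp(-(ax - 15000)^2 / 2e4), 1), delays, ax)
  fit <- fit_global(map, kinetic_scheme(700), instrument_model(30, 0),
                    fit_t0 = FALSE)
  expect_equal(fit$scheme$lifetimes, 1000, tolerance = 1e-6)
})

test_that("noiseless two-component fit recovers lifetimes and spectra", {
  ax <- seq(14000, 16000, by = 50)
  delays <- c(seq(-100, 2000, by = 50), seq(2200, 20000, by = 400))
  eas <- rbind(-exp(-(ax - 14800)^2 / 3e4), -1.4 * exp(-(ax - 15100)^2 / 5e4))
  map <- make_map(c(500, 5000), eas, delays, ax)
  fit <- fit_global(map, kinetic_scheme(c(300, 8000)), instrument_model(30, 0),
                    fit_t0 = FALSE)
  expect_equal(fit$scheme$lifetimes, c(500, 5000), tolerance = 1e-4)
  fitted_eas <- matrix(fit$eas$value, nrow = 2)
  expect_equal(fitted_eas, eas, tolerance = 1e-6, ignore_attr = TRUE)
  # reconstruction: model + residual = data exactly
  expect_equal(fit$fitted_map$dA + fit$residual_matrix, map$dA,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_lt(max(abs(fit$residual_matrix)), 1e-8)
})

test_that("variable projection equals a brute-force full nonlinear fit", {
  ax <- seq(1, 5)  # five wavelengths
  delays <- seq(-50, 4000, by = 50)
  eas <- rbind(c(1, .5, -.2, -.8, .3), c(-.4, .9, .7, -.1, -.6))
  map <- make_map(c(300, 2500), eas, delays, ax)
  vp <- fit_global(map, kinetic_scheme(c(200, 3000)), instrument_model(30, 0),
                   fit_t0 = FALSE)
  # brute force: lifetimes and all ten spectral amplitudes as free parameters
  bf_resid <- function(p) {
    taus <- exp(p[1:2])
    A <- matrix(p[3:12], nrow = 2)
    C <- concentration_profiles(kinetic_scheme(taus, "sequential"), delays, 30)
    as.vector(map$dA - C %*% A)
  }
  bf <- minpack.lm::nls.lm(par = c(log(c(200, 3000)), rep(0, 10)), fn = bf_resid,
                           control = minpack.lm::nls.lm.control(maxiter = 500))
  expect_equal(vp$scheme$lifetimes, exp(bf$par[1:2]), tolerance = 1e-6)
  expect_equal(matrix(vp$eas$value, nrow = 2), matrix(bf$par[3:12], nrow = 2),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("chirped data are fitted on the shifted time base", {
  ax <- seq(14000, 18000, by = 250)
  delays <- seq(-200, 3000, by = 40)
  eas <- rbind(-exp(-(ax - 15000)^2 / 3e4), -1.2 * exp(-(ax - 15400)^2 / 6e4))
  chirp <- c(0, 20, 4)  # strongly wavelength-dependent time zero
  map <- make_map(c(400, 4000), eas, delays, ax, chirp = chirp)
  inst <- instrument_model(30, 0, chirp)
  fit <- fit_global(map, kinetic_scheme(c(250, 6000)), inst, fit_t0 = FALSE)
  expect_equal(fit$scheme$lifetimes, c(400, 4000), tolerance = 1e-5)
  expect_lt(max(abs(fit$residual_matrix)), 1e-8)
})

test_that("order selection finds the true order of noiseless data", {
  ax <- seq(14000, 16000, by = 100)
  delays <- c(seq(-100, 2000, by = 50), seq(2200, 30000, by = 500))
  eas <- rbind(-exp(-(ax - 14800)^2 / 3e4), -1.4 * exp(-(ax - 15200)^2 / 5e4))
  map <- make_map(c(500, 5000), eas, delays, ax)
  sel <- select_order(map, orders = 1:4)
  expect_identical(sel$selected, 2L)
})

test_that("fastest fixture lifetime is recovered without bias at 1% noise", {
  init <- kinetic_scheme(c(150, 1500, 12000, 5e6), "sequential",
                         fixed = c(FALSE, FALSE, FALSE, TRUE))
  taus <- vapply(1:8, function(s) {
    map <- ta_fixture("acetone_B", noise_fraction = 0.01, seed = s)
    fit_global(map, init, instrument_model(30, 0))$scheme$lifetimes[1]
  }, numeric(1))
  expect_lt(abs(mean(taus) / 110 - 1), 0.05)   # relative bias
  expect_lt(stats::sd(taus) / 110, 0.10)       # seed-to-seed spread
})

test_that("fit diagnostics surface through tidy and glance", {
  map <- ta_fixture("acetone_Q", noise_fraction = 0.01, seed = 2)
  init <- kinetic_scheme(c(300, 4000, 5e6), "sequential",
                         fixed = c(FALSE, FALSE, TRUE))
  fit <- fit_global(map, init, instrument_model(30, 0))
  td <- tidy(fit)
  expect_identical(nrow(td), 3L)
  expect_true(all(is.na(td$std_error_fs[td$fixed])))
  # the small-amplitude middle component carries the largest relative error
  rel <- td$std_error_fs / td$lifetime_fs
  expect_gt(rel[2], rel[1])
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_gt(gl$rss, 0)
})

test_that("ill-posed designs are reported", {
  ax <- seq(14000, 15000, by = 100)
  map <- make_map(500, matrix(-exp(-(ax - 14500)^2 / 3e4), 1),
                  seq(-100, 3000, by = 50), ax)
  expect_warning(
    fit_global(map, kinetic_scheme(c(490, 500)), instrument_model(30, 0),
               fit_t0 = FALSE),
    "ill-conditioned"
  )
})
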