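#' Poisson Franck-Condon progression weights
#'
#' Intensities of a displaced-oscillator vibronic progression follow the
#' Poisson distribution in the Huang-Rhys factor S:
#' \eqn{w_n = e^{-S} S^n / n!}, n = 0, 1, ....
#'
#' @param huang_rhys Dimensionless Huang-Rhys factor S >= 0.
#' @param n_quanta Number of sub-bands (>= 1) to return, n = 0..n_quanta-1.
#' @return Numeric vector of `n_quanta` positive weights.
#' @examples
#' fc_progression(0.3, 2) # ratio w1/w0 equals S
#' @export
fc_progression <- function(huang_rhys, n_quanta) {
  if (!is.finite(huang_rhys) || huang_rhys < 0) {
    stop("huang_rhys must be a finite non-negative number", call. = FALSE)
  }
  if (!is.finite(n_quanta) || n_quanta < 1 || n_quanta != round(n_quanta)) {
    stop("n_quanta must be a positive integer", call. = FALSE)
  }
  stats::dpois(seq_len(n_quanta) - 1, lambda = huang_rhys)
}

#' Define a vibronic band
#'
#' One electronic transition with its vibronic progression: a 0-0 origin
#' `e00`, mode spacing `omega_vib`, Huang-Rhys factor `huang_rhys`, Gaussian
#' sub-band width `sigma` (all cm^-1), the angle `tdm_angle` of this band's
#' transition dipole to the reference dipole (degrees), and a peak `amplitude`.
#'
#' @param e00 0-0 transition energy, cm^-1.
#' @param omega_vib Vibronic spacing, cm^-1, > 0.
#' @param huang_rhys Huang-Rhys factor S >= 0.
#' @param sigma Gaussian width (standard deviation) of each sub-band, cm^-1, > 0.
#' @param tdm_angle Angle to the reference TDM, degrees in `[0, 90]`.
#' @param amplitude Peak scaling >= 0.
#' @param n_quanta Number of vibronic sub-bands >= 1.
#' @param label Optional band name (e.g. "Qy").
#' @return A `vibronic_band` list.
#' @export
vibronic_band <- function(e00, omega_vib, huang_rhys, sigma,
                          tdm_angle = 0, amplitude = 1, n_quanta = 4,
                          label = NULL) {
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (omega_vib <= 0) stop("omega_vib must be > 0", call. = FALSE)
  if (amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  if (huang_rhys < 0) stop("huang_rhys must be >= 0", call. = FALSE)
  if (tdm_angle < 0 || tdm_angle > 90) {
    stop("tdm_angle must lie in [0, 90] degrees", call. = FALSE)
  }
  structure(
    list(e00 = e00, omega_vib = omega_vib, huang_rhys = huang_rhys,
         sigma = sigma, tdm_angle = tdm_angle, amplitude = amplitude,
         n_quanta = as.integer(n_quanta), label = label),
    class = "vibronic_band"
  )
}

#' Render a vibronic band on a wavenumber axis
#'
#' Sum over sub-bands n of \eqn{w_n \exp(-(\tilde\nu - E_{00} - n\omega)^2 / 2\sigma^2)},
#' with Poisson Franck-Condon weights, rescaled so the global maximum equals
#' the band amplitude. If the axis does not cover `e00` within 3 sigma the
#' result carries a `coverage_warning` attribute.
#'
#' @param band A [vibronic_band()].
#' @param axis Strictly ascending wavenumber grid, cm^-1.
#' @return Spectrum tibble (domain "absorbance").
#' @export
make_vibronic_band <- function(band, axis) {
  stopifnot(inherits(band, "vibronic_band"))
  w <- fc_progression(band$huang_rhys, band$n_quanta)
  centers <- band$e00 + (seq_len(band$n_quanta) - 1) * band$omega_vib
  val <- rowSums(vapply(
    seq_along(w),
    function(i) w[[i]] * exp(-(axis - centers[[i]])^2 / (2 * band$sigma^2)),
    numeric(length(axis))
  ))
  if (band$amplitude == 0) {
    val <- rep(0, length(axis))
  } else {
    # normalize against the continuous-profile maximum so amplitude means
    # peak height irrespective of grid placement
    prof_fn <- function(x) {
      out <- 0
      for (i in seq_along(w)) {
        out <- out + w[[i]] * exp(-(x - centers[[i]])^2 / (2 * band$sigma^2))
      }
      out
    }
    fine <- seq(min(centers) - 4 * band$sigma, max(centers) + 4 * band$sigma,
                length.out = 4096)
    prof <- prof_fn(fine)
    ipk <- which.max(prof)
    step <- fine[2] - fine[1]
    pk <- stats::optimize(function(x) prof_fn(x), maximum = TRUE,
                          lower = fine[ipk] - step, upper = fine[ipk] + step,
                          tol = 1e-8)$objective
    val <- band$amplitude * val / pk
  }
  out <- spectrum_tbl(axis, val, domain = "absorbance")
  if (band$e00 - 3 * band$sigma < min(axis) || band$e00 + 3 * band$sigma > max(axis)) {
    attr(out, "coverage_warning") <- TRUE
  }
  out
}

#' Band systems
#'
#' An ordered collection of [vibronic_band()]s (e.g. Qy, Qx, Bx, By) whose
#' spectra superpose into a full absorption / excitation spectrum.
#'
#' @param ... `vibronic_band` objects, optionally named.
#' @return A `band_system` list.
#' @export
band_system <- function(...) {
  bands <- list(...)
  if (length(bands) == 1 && is.list(bands[[1]]) && !inherits(bands[[1]], "vibronic_band")) {
    bands <- bands[[1]]
  }
  if (length(bands) == 0) stop("band system must be non-empty", call. = FALSE)
  ok <- vapply(bands, inherits, logical(1), what = "vibronic_band")
  if (!all(ok)) stop("all elements must be vibronic_band objects", call. = FALSE)
  labels <- vapply(seq_along(bands), function(i) {
    nm <- names(bands)[i]
    if (!is.null(nm) && nzchar(nm)) nm else bands[[i]]$label %||% paste0("band", i)
  }, character(1))
  names(bands) <- labels
  structure(list(bands = bands), class = "band_system")
}

#' Superpose a band system on an axis
#'
#' @param system A [band_system()].
#' @param axis Wavenumber grid, cm^-1.
#' @return Spectrum tibble: sum of all band spectra.
#' @export
system_spectrum <- function(system, axis) {
  stopifnot(inherits(system, "band_system"))
  parts <- lapply(system$bands, make_vibronic_band, axis = axis)
  total <- Reduce(`+`, lapply(parts, function(s) s$value))
  spectrum_tbl(axis, total, domain = "absorbance")
}

#' Per-band intensity table for a band system
#'
#' Long tibble of each band's contribution on the axis, used by the
#' anisotropy generator for intensity-weighted averages.
#'
#' @inheritParams system_spectrum
#' @return Tibble with columns `band`, `tdm_angle`, `wavenumber`, `value`.
#' @export
system_components <- function(system, axis) {
  stopifnot(inherits(system, "band_system"))
  purrr::imap_dfr(system$bands, function(b, nm) {
    s <- make_vibronic_band(b, axis)
    tibble::tibble(band = nm, tdm_angle = b$tdm_angle,
                   wavenumber = s$wavenumber, value = s$value)
  })
}

#' Load a band system from a YAML description
#'
#' The YAML maps band names to `vibronic_band` fields. The packaged file
#' `chl_a_bands.yaml` holds the frozen chlorophyll-a-like defaults used by
#' the steady-state fixtures; its values are documented stand-ins shaped to
#' resemble measured low-temperature excitation spectra, not measured claims.
#'
#' @param path YAML file; defaults to the packaged chlorophyll-a band set.
#' @return A [band_system()].
#' @export
load_band_system <- function(path = chladyn_fixture("chl_a_bands.yaml")) {
  cfg <- yaml::read_yaml(path)
  bands <- purrr::imap(cfg$bands, function(b, nm) {
    vibronic_band(e00 = b$e00, omega_vib = b$omega_vib, huang_rhys = b$huang_rhys,
                  sigma = b$sigma, tdm_angle = b$tdm_angle,
                  amplitude = b$amplitude, n_quanta = b$n_quanta %||% 4,
                  label = nm)
  })
  band_system(bands)
}

#' Path to a packaged fixture file
#'
#' @param name File name under the package's `extdata/`.
#' @return Absolute path.
#' @export
chladyn_fixture <- function(name) {
  p <- system.file("extdata", name, package = "chladyn")
  if (!nzchar(p)) stop("no packaged fixture named ", name, call. = FALSE)
  p
}
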