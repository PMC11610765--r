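#' Kinetic scheme
#'
#' Compartmental first-order model: `sequential` (1 -> 2 -> ... -> n -> ground)
#' or `parallel` (independent decays). Lifetimes are stored in femtoseconds;
#' `fixed` marks lifetimes held constant during fitting (the long terminal
#' component is typically fixed when the delay window cannot constrain it).
#'
#' @param lifetimes Positive lifetimes, fs.
#' @param topology "sequential" or "parallel".
#' @param fixed Logical vector (recycled) marking fixed lifetimes.
#' @return A `kinetic_scheme` list.
#' @export
kinetic_scheme <- function(lifetimes, topology = c("sequential", "parallel"),
                           fixed = FALSE) {
  topology <- match.arg(topology)
  if (any(!is.finite(lifetimes)) || any(lifetimes <= 0)) {
    stop("all lifetimes must be positive and finite", call. = FALSE)
  }
  structure(
    list(lifetimes = as.numeric(lifetimes), topology = topology,
         fixed = rep_len(as.logical(fixed), length(lifetimes))),
    class = "kinetic_scheme"
  )
}

#' Gaussian instrument response model
#'
#' @param irf_fwhm Gaussian IRF full width at half maximum, fs (> 0); 0 is
#'   accepted as the no-IRF limit.
#' @param t0 Global time zero, fs.
#' @param chirp_coeffs Polynomial coefficients (degree <= 3, intercept first)
#'   of the wavenumber-dependent time-zero shift, evaluated in the reduced
#'   variable (wavenumber - chirp_center)/1000 so coefficients stay O(1)-O(10) fs.
#' @param chirp_center Centre wavenumber of the chirp polynomial, cm^-1.
#' @return An `instrument_model` list.
#' @export
instrument_model <- function(irf_fwhm = 30, t0 = 0, chirp_coeffs = 0,
                             chirp_center = 18000) {
  if (irf_fwhm < 0) stop("irf_fwhm must be >= 0", call. = FALSE)
  if (length(chirp_coeffs) > 4) stop("chirp polynomial degree must be <= 3", call. = FALSE)
  structure(list(irf_fwhm = irf_fwhm, t0 = t0,
                 chirp_coeffs = as.numeric(chirp_coeffs),
                 chirp_center = chirp_center),
            class = "instrument_model")
}

#' Time zero as a function of wavenumber
#'
#' @param instrument An [instrument_model()].
#' @param wavenumber Wavenumbers, cm^-1.
#' @return t0 values, fs.
#' @export
chirp_t0 <- function(instrument, wavenumber) {
  u <- (wavenumber - instrument$chirp_center) / 1000
  shift <- 0
  for (k in seq_along(instrument$chirp_coeffs)) {
    shift <- shift + instrument$chirp_coeffs[[k]] * u^(k - 1)
  }
  instrument$t0 + shift
}

#' Exponentially modified Gaussian decay basis
#'
#' Analytic convolution of a single-exponential decay (lifetime `tau`) with a
#' Gaussian IRF of standard deviation sigma = fwhm / (2 sqrt(2 ln 2)) centred
#' at `t0`:
#' \deqn{E(t) = \tfrac12 e^{(\sigma^2/2\tau^2) - (t-t_0)/\tau}
#'       \mathrm{erfc}\!\left(\tfrac{\sigma}{\sqrt2\,\tau} - \tfrac{t-t_0}{\sqrt2\,\sigma}\right)}
#' evaluated in log space for numerical stability. It reduces to the pure
#' exponential step decay as fwhm -> 0, and equals half the step amplitude at
#' t = t0 in the narrow-IRF limit.
#'
#' @param t Delay times, fs.
#' @param tau Lifetime, fs, > 0.
#' @param irf_fwhm Gaussian IRF FWHM, fs (0 allowed).
#' @param t0 Time zero, fs.
#' @return Numeric vector, the IRF-convolved decay.
#' @export
emg_decay <- function(t, tau, irf_fwhm = 0, t0 = 0) {
  if (!is.finite(tau) || tau <= 0) stop("tau must be positive", call. = FALSE)
  td <- t - t0
  if (irf_fwhm <= 0) {
    return(ifelse(td >= 0, exp(-td / tau), 0))
  }
  sigma <- irf_fwhm / (2 * sqrt(2 * log(2)))
  k <- 1 / tau
  # 0.5*erfc(z/sqrt2) == pnorm(-z); use log form to avoid overflow of exp()
  log_g <- (sigma * k)^2 / 2 - k * td
  z <- sigma * k - td / sigma
  exp(log_g + stats::pnorm(-z, log.p = TRUE))
}

# Bateman coefficient matrix for a sequential chain with rates k_i = 1/tau_i:
# c_i(t) = sum_j B[i, j] * e_j(t), e_j the (IRF-convolved) exponential with
# lifetime tau_j. Requires distinct lifetimes.
.bateman_matrix <- function(lifetimes) {
  n <- length(lifetimes)
  k <- 1 / lifetimes
  if (n > 1 && min(abs(diff(sort(k)))) < 1e-12 * max(k)) {
    stop("sequential closed form requires distinct lifetimes", call. = FALSE)
  }
  B <- matrix(0, n, n)
  for (i in seq_len(n)) {
    pref <- if (i > 1) prod(k[seq_len(i - 1)]) else 1
    for (j in seq_len(i)) {
      denom <- prod(k[setdiff(seq_len(i), j)] - k[j])
      B[i, j] <- pref / ifelse(i == 1, 1, denom)
    }
  }
  B
}

#' Compartment concentration profiles
#'
#' Closed-form populations of a kinetic scheme convolved with the Gaussian
#' IRF: sequential chains use the Bateman solution expressed as a linear
#' combination of [emg_decay()] bases (exact, no ODE integration), parallel
#' schemes are independent EMG decays.
#'
#' @param scheme A [kinetic_scheme()].
#' @param t Delay times, fs.
#' @param irf_fwhm IRF FWHM, fs.
#' @param t0 Time zero, fs.
#' @return Matrix `length(t)` x n_compartments.
#' @export
concentration_profiles <- function(scheme, t, irf_fwhm = 0, t0 = 0) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  taus <- scheme$lifetimes
  E <- vapply(taus, function(tau) emg_decay(t, tau, irf_fwhm, t0),
              numeric(length(t)))
  E <- matrix(E, nrow = length(t))
  if (scheme$topology == "parallel") return(E)
  B <- .bateman_matrix(taus)
  E %*% t(B)
}

#' Convert between evolution- and decay-associated spectra
#'
#' For a sequential scheme the data admit two equivalent representations:
#' evolution-associated spectra (EAS, one per compartment of the chain) and
#' decay-associated spectra (DAS, one per exponential). The map is the exact
#' linear transform \eqn{DAS_j = \sum_{i \ge j} B_{ij} EAS_i} with B the
#' Bateman coefficient matrix; both reconstruct the data identically.
#'
#' @param eas,das Matrix (n_components x n_wavenumbers) or tibble in long
#'   form with columns `component`, `wavenumber`, `value`.
#' @param lifetimes Sequential lifetimes, fs (distinct).
#' @return Same shape as the input.
#' @export
eas_to_das <- function(eas, lifetimes) {
  .assoc_transform(eas, lifetimes, inverse = FALSE)
}

#' @rdname eas_to_das
#' @export
das_to_eas <- function(das, lifetimes) {
  .assoc_transform(das, lifetimes, inverse = TRUE)
}

.assoc_transform <- function(spectra, lifetimes, inverse) {
  long <- is.data.frame(spectra)
  if (long) {
    wide <- tidyr::pivot_wider(spectra, names_from = "wavenumber",
                               values_from = "value")
    comp <- wide$component
    M <- as.matrix(wide[setdiff(names(wide), "component")])
  } else {
    M <- as.matrix(spectra)
  }
  if (nrow(M) != length(lifetimes)) {
    stop("one spectrum per lifetime is required", call. = FALSE)
  }
  B <- .bateman_matrix(lifetimes)
  out <- if (inverse) solve(t(B), M) else t(B) %*% M
  if (!long) return(out)
  res <- tibble::as_tibble(out)
  res$component <- comp
  tidyr::pivot_longer(res, -"component", names_to = "wavenumber",
                      values_to = "value") |>
    dplyr::mutate(wavenumber = as.numeric(.data$wavenumber))
}
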