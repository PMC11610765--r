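#' Configuration of the coupled-surface wavepacket model
#'
#' Five electronic states (S0, Qy, Qx, Bx, By) on two-dimensional nested model
#' potentials: identical-curvature harmonic wells in the two dimensionless
#' normal-mode coordinates (default mode frequencies 1489 and 1639 cm^-1, the
#' modes with the largest projection on the non-adiabatic coupling vector),
#' offset vertically by the state energies, with symmetric inter-state
#' couplings that are either constant or Gaussian-shaped in the coordinates.
#' Couplings localized off the Franck-Condon point are what allow vibronically
#' quasi-resonant inter-band transfer; strictly constant couplings on nested
#' identical wells decouple electronic from nuclear motion entirely (see the
#' methods vignette).
#'
#' @param path YAML file; defaults to the packaged, calibrated-then-frozen
#'   model `qd_default.yaml`.
#' @return A `qd_config` list.
#' @export
qd_config <- function(path = chladyn_fixture("qd_default.yaml")) {
  cfg <- yaml::read_yaml(path)
  cfg$mode_freqs <- as.numeric(cfg$mode_freqs %||% c(1489, 1639))
  cfg$grid$n <- as.integer(cfg$grid$points %||% c(64, 64))
  cfg$grid$qmax <- as.numeric(cfg$grid$qmax %||% 6)
  if (any(cfg$grid$n %% 2 != 0)) stop("grid sizes must be even for FFT", call. = FALSE)
  cfg$dt <- as.numeric(cfg$dt %||% 0.1)
  cfg$t_final <- as.numeric(cfg$t_final %||% 500)
  cfg$record_every <- as.integer(cfg$record_every %||% 10)
  states <- c("S0", "Qy", "Qx", "Bx", "By")
  if (!all(states %in% names(cfg$state_energies))) {
    stop("state_energies must name S0, Qy, Qx, Bx, By", call. = FALSE)
  }
  cfg$state_energies <- vapply(states, function(s) as.numeric(cfg$state_energies[[s]]),
                               numeric(1))
  for (cp in cfg$couplings) {
    if (!all(cp$states %in% states)) {
      stop("unknown state in coupling pair: ", paste(cp$states, collapse = "-"),
           call. = FALSE)
    }
  }
  structure(cfg, class = "qd_config")
}

.qd_states <- c("S0", "Qy", "Qx", "Bx", "By")

# evaluate a coupling's spatial profile on flattened grid coordinates
.coupling_profile <- function(cp, q1, q2) {
  shape <- cp$shape$type %||% "constant"
  v <- as.numeric(cp$value)
  if (shape == "constant") {
    rep(v, length(q1))
  } else if (shape == "gaussian") {
    ctr <- as.numeric(cp$shape$center %||% c(0, 0))
    w <- as.numeric(cp$shape$width %||% 1)
    v * exp(-((q1 - ctr[1])^2 + (q2 - ctr[2])^2) / (2 * w^2))
  } else {
    stop("unknown coupling shape: ", shape, call. = FALSE)
  }
}

#' Build the model Hamiltonian on the grid
#'
#' Assembles the 5x5 potential matrix at every grid point (identical harmonic
#' diagonal wells offset by the state energies, symmetric couplings per the
#' config) and diagonalises it pointwise, yielding the adiabatic surfaces,
#' eigenvectors, and everything the split-operator propagator needs.
#'
#' @param config A [qd_config()].
#' @return A `qd_hamiltonian` list: grids, vibrational potential, adiabatic
#'   `evals` (npts x 5, ascending), `evecs` (npts x 5 x 5), kinetic grid,
#'   and FC-point diagnostics (`fc_gaps`, adiabatic gaps at the origin).
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "qd_config"))
  n1 <- config$grid$n[1]; n2 <- config$grid$n[2]
  qmax <- config$grid$qmax
  if (qmax < 5 / sqrt(2)) {
    stop("grid extent must cover at least 5 coordinate sd of the ground vibrational state",
         call. = FALSE)
  }
  dq1 <- 2 * qmax / n1; dq2 <- 2 * qmax / n2
  q1 <- -qmax + dq1 * (seq_len(n1) - 1)
  q2 <- -qmax + dq2 * (seq_len(n2) - 1)
  G <- expand.grid(q1 = q1, q2 = q2)  # column-major: q1 fastest
  npts <- n1 * n2
  hw <- config$mode_freqs * .cm1_to_ev  # hbar*omega in eV
  vib <- 0.5 * hw[1] * G$q1^2 + 0.5 * hw[2] * G$q2^2

  E <- config$state_energies
  M <- array(0, dim = c(npts, 5, 5))
  for (s in 1:5) M[, s, s] <- E[[s]]
  for (cp in config$couplings) {
    i <- match(cp$states[[1]], .qd_states)
    j <- match(cp$states[[2]], .qd_states)
    prof <- .coupling_profile(cp, G$q1, G$q2)
    M[, i, j] <- M[, i, j] + prof
    M[, j, i] <- M[, j, i] + prof
  }
  evals <- matrix(0, npts, 5)
  evecs <- array(0, dim = c(npts, 5, 5))
  for (p in seq_len(npts)) {
    eg <- eigen(M[p, , ], symmetric = TRUE)
    # eigen() returns descending eigenvalues; store ascending
    ord <- 5:1
    evals[p, ] <- eg$values[ord]
    evecs[p, , ] <- eg$vectors[, ord]
  }
  # kinetic energy on the momentum grid: T = sum_k hbar*omega_k p_k^2 / 2
  pgrid <- function(n, dq) 2 * pi / (n * dq) * c(0:(n / 2 - 1), -(n / 2):-1)
  p1 <- pgrid(n1, dq1); p2 <- pgrid(n2, dq2)
  Tkin <- outer(0.5 * hw[1] * p1^2, 0.5 * hw[2] * p2^2, `+`)

  fc <- which(abs(G$q1) < dq1 / 4 & abs(G$q2) < dq2 / 4)[1]
  if (is.na(fc)) fc <- which.min(G$q1^2 + G$q2^2)[1]
  fc_e <- evals[fc, ]
  structure(
    list(config = config, n1 = n1, n2 = n2, npts = npts,
         q1 = q1, q2 = q2, dq = dq1 * dq2, qgrid = G,
         vib = vib, diabatic = M, evals = evals, evecs = evecs,
         Tkin = Tkin, hw = hw, fc_index = fc,
         fc_energies = stats::setNames(fc_e, .qd_states),
         fc_gaps = stats::setNames(diff(fc_e), paste(.qd_states[-5], .qd_states[-1],
                                                     sep = "-"))),
    class = "qd_hamiltonian"
  )
}

#' @export
print.qd_hamiltonian <- function(x, ...) {
  cat(sprintf("qd_hamiltonian: 5 states on %dx%d grid, |q| <= %g\n",
              x$n1, x$n2, x$config$grid$qmax))
  cat("  adiabatic FC energies (eV):",
      paste(sprintf("%s=%.4f", .qd_states, x$fc_energies), collapse = ", "), "\n")
  cat(sprintf("  adiabatic Qx-Qy FC gap: %.4f eV\n",
              x$fc_energies[["Qx"]] - x$fc_energies[["Qy"]]))
  invisible(x)
}

#' Initial wavefunctions
#'
#' `qd_ground_state()` places the ground vibrational Gaussian of the
#' (identical) wells on one diabatic state, optionally displaced - a delta
#' (Condon) excitation when placed on an excited state.
#'
#' @param H A `qd_hamiltonian`.
#' @param state Diabatic state carrying the wavepacket.
#' @param displace Length-2 coordinate displacement of the Gaussian.
#' @return Complex matrix npts x 5, grid-normalised.
#' @export
qd_ground_state <- function(H, state = "S0", displace = c(0, 0)) {
  s <- match.arg(state, .qd_states)
  g <- exp(-((H$qgrid$q1 - displace[1])^2 + (H$qgrid$q2 - displace[2])^2) / 2)
  g <- g / sqrt(sum(abs(g)^2) * H$dq)
  psi <- matrix(0 + 0i, H$npts, 5)
  psi[, match(s, .qd_states)] <- g
  psi
}

# pointwise application of the precomputed 5x5 propagator stack
.apply_pointwise <- function(U, psi) {
  out <- psi
  for (i in 1:5) {
    acc <- U[, i, 1] * psi[, 1]
    for (j in 2:5) acc <- acc + U[, i, j] * psi[, j]
    out[, i] <- acc
  }
  out
}

# build exp(-1i * (vib + V_el) * dt / hbar) pointwise from the eigensystem
.potential_propagator <- function(H, dt) {
  ph <- exp(-1i * (H$vib + H$evals) * dt / .hbar_ev_fs)  # npts x 5 (recycled vib)
  U <- array(0i, dim = c(H$npts, 5, 5))
  for (i in 1:5) for (j in 1:5) {
    acc <- H$evecs[, i, 1] * ph[, 1] * H$evecs[, j, 1]
    for (a in 2:5) acc <- acc + H$evecs[, i, a] * ph[, a] * H$evecs[, j, a]
    U[, i, j] <- acc
  }
  U
}

.kinetic_phase <- function(H, dt) exp(-1i * H$Tkin * dt / .hbar_ev_fs)

.fft2 <- function(v, n1, n2, inverse = FALSE) {
  dim(v) <- c(n1, n2)
  out <- stats::fft(v, inverse = inverse)
  if (inverse) out <- out / (n1 * n2)
  as.vector(out)
}

.apply_kinetic <- function(psi, K, n1, n2) {
  for (s in 1:5) {
    v <- .fft2(psi[, s], n1, n2)
    dim(v) <- c(n1, n2)
    v <- v * K
    psi[, s] <- .fft2(as.vector(v), n1, n2, inverse = TRUE)
  }
  psi
}

.populations <- function(H, psi, basis = c("adiabatic", "diabatic")) {
  basis <- match.arg(basis)
  if (basis == "diabatic") {
    colSums(abs(psi)^2) * H$dq
  } else {
    pops <- numeric(5)
    for (a in 1:5) {
      phi <- H$evecs[, 1, a] * psi[, 1]
      for (i in 2:5) phi <- phi + H$evecs[, i, a] * psi[, i]
      pops[a] <- sum(abs(phi)^2) * H$dq
    }
    pops
  }
}

.total_energy <- function(H, psi) {
  pot <- 0
  for (a in 1:5) {
    phi <- H$evecs[, 1, a] * psi[, 1]
    for (i in 2:5) phi <- phi + H$evecs[, i, a] * psi[, i]
    pot <- pot + sum((H$vib + H$evals[, a]) * abs(phi)^2) * H$dq
  }
  kin <- 0
  for (s in 1:5) {
    a <- .fft2(psi[, s], H$n1, H$n2)
    kin <- kin + sum(H$Tkin * abs(matrix(a, H$n1, H$n2))^2)
  }
  # Parseval: |fft|^2 sums to npts * |psi|^2; normalise to the grid measure
  kin <- kin * H$dq / (H$n1 * H$n2)
  pot + kin
}

#' Propagate a wavepacket
#'
#' Second-order (Strang) split-operator propagation alternating the kinetic
#' propagator in momentum space (FFT) with the exact pointwise exponential of
#' the 5x5 potential matrix. Norm is monitored every recorded step and a
#' drift beyond `norm_tol` aborts with a stability error naming dt/grid.
#'
#' @param H A `qd_hamiltonian` from [build_model()].
#' @param psi0 Initial wavefunction (npts x 5 complex), e.g. from
#'   [qd_ground_state()].
#' @param t_final,dt,record_every Override the config values.
#' @param record_autocorrelation Also record `<psi0 | psi(t)>`.
#' @param norm_tol Permitted norm drift.
#' @return A `qd_trace`: tibble `populations` (time, state, population,
#'   basis), `norm`, `energy` tibbles, final `psi`.
#' @export
propagate <- function(H, psi0, t_final = NULL, dt = NULL, record_every = NULL,
                      record_autocorrelation = FALSE, norm_tol = 1e-6) {
  stopifnot(inherits(H, "qd_hamiltonian"))
  cfg <- H$config
  t_final <- t_final %||% cfg$t_final
  dt <- dt %||% cfg$dt
  record_every <- record_every %||% cfg$record_every
  espan <- diff(range(H$evals)) + max(H$vib)
  if (dt * espan / .hbar_ev_fs > 3) {
    stop(sprintf("dt = %g fs does not resolve the energy span %.3g eV; reduce dt or the grid extent",
                 dt, espan), call. = FALSE)
  }
  nsteps <- ceiling(t_final / dt)
  UV <- .potential_propagator(H, dt)
  Kh <- .kinetic_phase(H, dt / 2)
  psi <- psi0
  norm0 <- sum(abs(psi)^2) * H$dq

  rec_t <- 0
  n_rec <- floor(nsteps / record_every) + 1
  times <- numeric(n_rec)
  pop_ad <- matrix(0, n_rec, 5)
  pop_di <- matrix(0, n_rec, 5)
  norms <- numeric(n_rec)
  energies <- numeric(n_rec)
  auto <- if (record_autocorrelation) complex(n_rec) else NULL
  rec <- function(k, t) {
    times[k] <<- t
    pop_ad[k, ] <<- .populations(H, psi, "adiabatic")
    pop_di[k, ] <<- .populations(H, psi, "diabatic")
    norms[k] <<- sum(abs(psi)^2) * H$dq
    energies[k] <<- .total_energy(H, psi)
    if (record_autocorrelation) auto[k] <<- sum(Conj(psi0) * psi) * H$dq
  }
  rec(1, 0)
  k <- 2
  for (step in seq_len(nsteps)) {
    psi <- .apply_kinetic(psi, Kh, H$n1, H$n2)
    psi <- .apply_pointwise(UV, psi)
    psi <- .apply_kinetic(psi, Kh, H$n1, H$n2)
    if (step %% record_every == 0) {
      rec(k, step * dt)
      if (abs(norms[k - 0] / norm0 - 1) > norm_tol) {
        stop(sprintf("norm drift %.3g exceeds %.1g at t = %.1f fs: reduce dt (%g fs) or enlarge the %dx%d grid",
                     abs(norms[k] / norm0 - 1), norm_tol, step * dt, dt, H$n1, H$n2),
             call. = FALSE)
      }
      k <- k + 1
    }
  }
  used <- seq_len(k - 1)
  pops <- dplyr::bind_rows(
    tibble::tibble(time = rep(times[used], 5),
                   state = rep(.qd_states, each = length(used)),
                   population = as.vector(pop_ad[used, ]),
                   basis = "adiabatic"),
    tibble::tibble(time = rep(times[used], 5),
                   state = rep(.qd_states, each = length(used)),
                   population = as.vector(pop_di[used, ]),
                   basis = "diabatic")
  )
  structure(
    list(populations = pops,
         norm = tibble::tibble(time = times[used], norm = norms[used]),
         energy = tibble::tibble(time = times[used], energy = energies[used]),
         autocorrelation = if (record_autocorrelation) {
           tibble::tibble(time = times[used], autocorrelation = auto[used])
         },
         psi = psi, dt = dt, t_final = t_final),
    class = "qd_trace"
  )
}

#' Summed band population and its 1/e decay time
#'
#' @param trace A `qd_trace`.
#' @param states States whose adiabatic populations are summed (default the
#'   B band).
#' @return `band_population()`: tibble (time, population);
#'   `efold_time()`: first time the summed population falls to 1/e of its
#'   initial value (`Inf` if it never does within the trace).
#' @export
band_population <- function(trace, states = c("Bx", "By")) {
  trace$populations |>
    dplyr::filter(.data$basis == "adiabatic", .data$state %in% states) |>
    dplyr::summarise(population = sum(.data$population), .by = "time")
}

#' @rdname band_population
#' @export
efold_time <- function(trace, states = c("Bx", "By")) {
  bp <- band_population(trace, states)
  target <- bp$population[[1]] / exp(1)
  below <- which(bp$population <= target)
  if (length(below) == 0) return(Inf)
  i <- below[[1]]
  if (i == 1) return(bp$time[[1]])
  # linear interpolation between the bracketing records
  t1 <- bp$time[[i - 1]]; t2 <- bp$time[[i]]
  p1 <- bp$population[[i - 1]]; p2 <- bp$population[[i]]
  t1 + (p1 - target) / (p1 - p2) * (t2 - t1)
}

#' Zero (or restore) a coupling between states or bands
#'
#' `pair` may name individual states ("Bx", "Qx") or whole bands ("B", "Q");
#' bands expand to both their members. Toggling off sets the matched
#' couplings' values to zero but remembers the original, so toggling back on
#' restores the exact config.
#'
#' @param config A [qd_config()].
#' @param pair Character length-2, e.g. `c("B", "Qx")`.
#' @param off TRUE to zero the coupling, FALSE to restore it.
#' @return Modified `qd_config`.
#' @export
toggle_coupling <- function(config, pair, off = TRUE) {
  stopifnot(inherits(config, "qd_config"), length(pair) == 2)
  expand <- function(x) {
    switch(x, B = c("Bx", "By"), Q = c("Qx", "Qy"),
           { if (!x %in% .qd_states) stop("unknown state or band: ", x, call. = FALSE); x })
  }
  g1 <- expand(pair[[1]]); g2 <- expand(pair[[2]])
  hit <- FALSE
  for (i in seq_along(config$couplings)) {
    st <- config$couplings[[i]]$states
    if ((st[[1]] %in% g1 && st[[2]] %in% g2) || (st[[1]] %in% g2 && st[[2]] %in% g1)) {
      hit <- TRUE
      if (off) {
        if (is.null(config$couplings[[i]]$value_orig)) {
          config$couplings[[i]]$value_orig <- config$couplings[[i]]$value
        }
        config$couplings[[i]]$value <- 0
      } else if (!is.null(config$couplings[[i]]$value_orig)) {
        config$couplings[[i]]$value <- config$couplings[[i]]$value_orig
        config$couplings[[i]]$value_orig <- NULL
      }
    }
  }
  if (!hit) stop("no coupling matches pair ", paste(pair, collapse = "-"), call. = FALSE)
  config
}

#' Pump-pulse excitation
#'
#' Adds the semiclassical dipole interaction -mu.E(t) to the propagator and
#' runs through the pulse: a Gaussian envelope (FWHM `fwhm` fs) with carrier
#' energy `omega0` (eV) and peak field in GV/cm; transition dipoles in atomic
#' units couple the named state pairs. The dipole term is a single 5x5
#' matrix, applied via its eigendecomposition between potential half-steps.
#'
#' @param H A `qd_hamiltonian`.
#' @param pulse List with `peak_field` (GV/cm), `fwhm` (fs), `omega0` (eV),
#'   `dipoles` (named list like `"S0-By" = 2.0`, atomic units); defaults come
#'   from the config's `pulse` block.
#' @param psi0 Initial wavefunction (default: vibrational ground state on S0).
#' @param t_end Propagation end, fs (default: pulse centre + 2 FWHM).
#' @param dt Time step, fs.
#' @return List: `psi` (wavefunction at `t_end`), `populations` (adiabatic,
#'   at `t_end`), `excited_population` (1 - P(S0)), `b_population`
#'   (P(Bx)+P(By)), `trace` (a `qd_trace` over the pulse).
#' @export
apply_pulse <- function(H, pulse = NULL, psi0 = NULL, t_end = NULL, dt = NULL) {
  stopifnot(inherits(H, "qd_hamiltonian"))
  pulse <- pulse %||% H$config$pulse
  if (is.null(pulse)) stop("no pulse given and none in the config", call. = FALSE)
  dt <- dt %||% min(H$config$dt, 0.05)
  fwhm <- as.numeric(pulse$fwhm %||% 20)
  e0 <- as.numeric(pulse$peak_field %||% 0.0026)
  om0 <- as.numeric(pulse$omega0 %||% 3.60)
  trans <- H$fc_energies - H$fc_energies[["S0"]]
  if (all(abs(om0 - trans[-1]) > 1)) {
    warning(sprintf("pulse carrier %.2f eV is detuned > 1 eV from every transition", om0))
  }
  sig <- fwhm / (2 * sqrt(2 * log(2)))
  tc <- 3 * fwhm
  t_end <- t_end %||% (tc + 2 * fwhm)
  if (is.null(psi0)) psi0 <- qd_ground_state(H, "S0")

  # dipole matrix in eV per (GV/cm): 1 a.u. dipole x 1 GV/cm = 5.2918 eV
  D <- matrix(0, 5, 5)
  for (nm in names(pulse$dipoles %||% list())) {
    ij <- match(strsplit(nm, "-")[[1]], .qd_states)
    if (anyNA(ij) || length(ij) != 2) stop("bad dipole pair name: ", nm, call. = FALSE)
    D[ij[1], ij[2]] <- D[ij[1], ij[2]] + 5.29177 * as.numeric(pulse$dipoles[[nm]])
    D[ij[2], ij[1]] <- D[ij[1], ij[2]]
  }
  ed <- eigen(D, symmetric = TRUE)

  nsteps <- ceiling(t_end / dt)
  UVh <- .potential_propagator(H, dt / 2)
  Kh <- .kinetic_phase(H, dt / 2)
  psi <- psi0
  field <- function(t) e0 * exp(-(t - tc)^2 / (2 * sig^2)) * cos(om0 * (t - tc) / .hbar_ev_fs)
  rec_every <- max(1L, H$config$record_every)
  n_rec <- floor(nsteps / rec_every) + 1
  times <- numeric(n_rec); pop_ad <- matrix(0, n_rec, 5); norms <- numeric(n_rec)
  times[1] <- 0; pop_ad[1, ] <- .populations(H, psi, "adiabatic")
  norms[1] <- sum(abs(psi)^2) * H$dq
  k <- 2
  for (step in seq_len(nsteps)) {
    tmid <- (step - 0.5) * dt
    psi <- .apply_kinetic(psi, Kh, H$n1, H$n2)
    psi <- .apply_pointwise(UVh, psi)
    ph <- exp(1i * field(tmid) * ed$values * dt / .hbar_ev_fs)  # exp(-i(-E.D)dt/hbar)
    Uw <- ed$vectors %*% (ph * t(ed$vectors))
    psi <- psi %*% t(Uw)
    psi <- .apply_pointwise(UVh, psi)
    psi <- .apply_kinetic(psi, Kh, H$n1, H$n2)
    if (step %% rec_every == 0) {
      times[k] <- step * dt
      pop_ad[k, ] <- .populations(H, psi, "adiabatic")
      norms[k] <- sum(abs(psi)^2) * H$dq
      k <- k + 1
    }
  }
  used <- seq_len(k - 1)
  pops_end <- .populations(H, psi, "adiabatic")
  names(pops_end) <- .qd_states
  list(
    psi = psi,
    populations = pops_end,
    excited_population = 1 - pops_end[["S0"]],
    b_population = pops_end[["Bx"]] + pops_end[["By"]],
    trace = tibble::tibble(
      time = rep(times[used], 5),
      state = rep(.qd_states, each = length(used)),
      population = as.vector(pop_ad[used, ]),
      basis = "adiabatic"
    ),
    norm = tibble::tibble(time = times[used], norm = norms[used]),
    t_end = t_end, pulse = list(peak_field = e0, fwhm = fwhm, omega0 = om0,
                                center = tc)
  )
}
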