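#' Packaged synthetic-study fixtures
#'
#' Builders that turn the packaged YAML ground-truth descriptions into data:
#' steady-state excitation/emission + anisotropy sets, magic-angle TA maps
#' for B- and Q-band excitation in acetone, and the polarized pair used for
#' transient anisotropy decomposition. All stochastic output is seeded.
#'
#' @name chladyn-fixtures
NULL

.fixture_axis <- function(ax) seq(ax$from, ax$to, length.out = ax$points)

.fixture_delays <- function(d) {
  early <- seq(d$early$from, d$early$to, by = d$early$by)
  late <- if (!is.null(d$late)) {
    exp(seq(log(d$late$from), log(d$late$to), length.out = d$late$points))
  } else numeric(0)
  sort(unique(c(early, late)))
}

.species_spectrum <- function(sp, axis) {
  val <- rep(0, length(axis))
  for (g in sp$gaussians) {
    val <- val + g$amplitude * exp(-(axis - g$center)^2 / (2 * g$sigma^2))
  }
  spectrum_tbl(axis, val, domain = "delta_A")
}

.load_ta_fixture <- function(path) {
  cfg <- yaml::read_yaml(path)
  axis <- .fixture_axis(cfg$axis)
  list(
    cfg = cfg,
    scheme = kinetic_scheme(as.numeric(cfg$lifetimes_fs), cfg$topology,
                            as.logical(cfg$fixed)),
    instrument = instrument_model(cfg$irf_fwhm_fs, cfg$t0_fs),
    species = lapply(cfg$species, .species_spectrum, axis = axis),
    geometry = if (!is.null(cfg$species[[1]]$tdm_angle)) {
      pump_geometry(vapply(cfg$species, function(s) as.numeric(s$tdm_angle),
                           numeric(1)))
    },
    delays = .fixture_delays(cfg$delays),
    meta = list(excitation_band = cfg$excitation_band, solvent = cfg$solvent,
                fixture_version = cfg$fixture_version)
  )
}

#' @rdname chladyn-fixtures
#' @param noise_fraction White-noise level (sd as fraction of max signal).
#' @param seed Seed (required for noisy output).
#' @export
steady_state_fixture <- function(noise_fraction = 0, seed = NULL) {
  system <- load_band_system()
  axis <- seq(13800, 25400, by = 25)
  gen_steady_state_set(system, axis, noise_fraction = noise_fraction, seed = seed)
}

#' @rdname chladyn-fixtures
#' @param name "acetone_B" or "acetone_Q" (magic-angle maps).
#' @export
ta_fixture <- function(name = c("acetone_B", "acetone_Q"),
                       noise_fraction = 0.01, seed = 1L) {
  name <- match.arg(name)
  fx <- .load_ta_fixture(chladyn_fixture(sprintf("chl_a_%s.yaml", name)))
  gen_ta_map(fx$scheme, fx$species, fx$instrument, geometry = NULL,
             polarization = "magic", delays = fx$delays,
             noise_fraction = noise_fraction, seed = seed, meta = fx$meta)
}

#' @rdname chladyn-fixtures
#' @export
ta_fixture_truth <- function(name = c("acetone_B", "acetone_Q", "taa")) {
  name <- match.arg(name)
  .load_ta_fixture(chladyn_fixture(sprintf("chl_a_%s.yaml", name)))
}

#' @rdname chladyn-fixtures
#' @export
taa_fixture <- function(noise_fraction = 0.02, seed = 1L) {
  fx <- .load_ta_fixture(chladyn_fixture("chl_a_taa.yaml"))
  gen_taa_set(fx$scheme, fx$species, fx$instrument, fx$geometry, fx$delays,
              noise_fraction = noise_fraction, seed = seed, meta = fx$meta)
}
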