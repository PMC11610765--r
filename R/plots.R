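#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' @importFrom rlang .data
NULL

#' Quick-look plots
#'
#' `autoplot` methods for the package's result types: TA maps (filled delay x
#' wavenumber raster), decomposition components, global-fit EAS/DAS, QD
#' population traces and thermal temperature transients.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @name chladyn-autoplot
NULL

#' @rdname chladyn-autoplot
#' @export
autoplot.ta_map <- function(object, ...) {
  as_tibble(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$wavenumber, .data$delay, fill = .data$dA)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b") +
    ggplot2::labs(x = expression(wavenumber ~ (cm^-1)), y = "delay (fs)",
                  fill = expression(Delta * A ~ (mOD)),
                  title = sprintf("TA map (%s)", object$polarization))
}

#' @rdname chladyn-autoplot
#' @export
autoplot.pol_components <- function(object, ...) {
  dplyr::bind_rows(
    dplyr::mutate(object$s_parallel, component = "parallel"),
    dplyr::mutate(object$s_orthogonal, component = "orthogonal")
  ) |>
    ggplot2::ggplot(ggplot2::aes(.data$wavenumber, .data$value,
                                 colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(wavenumber ~ (cm^-1)), y = "intensity",
                  title = sprintf("polarization-associated components (beta = %.1f deg)",
                                  object$frame$beta))
}

#' @rdname chladyn-autoplot
#' @param which "eas" or "das".
#' @export
autoplot.global_fit <- function(object, which = c("eas", "das"), ...) {
  which <- match.arg(which)
  d <- object[[which]] |>
    dplyr::mutate(label = sprintf("tau = %s fs", signif(.data$lifetime, 3)))
  ggplot2::ggplot(d, ggplot2::aes(.data$wavenumber, .data$value,
                                  colour = .data$label)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(wavenumber ~ (cm^-1)),
                  y = expression(Delta * A ~ (mOD)),
                  colour = NULL, title = toupper(which))
}

#' @rdname chladyn-autoplot
#' @param basis Population basis to show.
#' @export
autoplot.qd_trace <- function(object, basis = "adiabatic", ...) {
  object$populations |>
    dplyr::filter(.data$basis == !!basis) |>
    ggplot2::ggplot(ggplot2::aes(.data$time, .data$population,
                                 colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (fs)", y = "population",
                  title = sprintf("%s state populations", basis))
}

#' @rdname chladyn-autoplot
#' @param config A [thermal_config()] (for `plot_tm`).
#' @param times Times, ps.
#' @export
plot_tm <- function(config, times = seq(0, 50, by = 0.05)) {
  simulate_Tm(config, times) |>
    ggplot2::ggplot(ggplot2::aes(.data$time, .data$T_m)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ps)", y = expression(T[m] ~ (K)),
                  title = "effective molecular temperature")
}
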