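#' Plot a parameter sweep
#'
#' @param object An `nw_sweep` from [sweep_sensitivity()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot nw_sweep
#' @export
autoplot.nw_sweep <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$param_value, .data$sensitivity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = attr(object, "parameter"),
                  y = expression(Delta * G / G[0]),
                  title = "Sensitivity sweep") +
    ggplot2::theme_minimal()
}

#' Plot a pH-response curve
#'
#' Sensitivity versus pH, with the net analyte charge as a secondary
#' dashed curve (right axis, rescaled).
#'
#' @param object An `nw_ph_response` from [ph_response()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot nw_ph_response
#' @export
autoplot.nw_ph_response <- function(object, ...) {
  d <- as_tibble(object)
  scale <- max(abs(d$sensitivity)) / max(abs(d$net_charge_e), 1e-12)
  ggplot2::ggplot(d, ggplot2::aes(.data$pH, .data$sensitivity)) +
    ggplot2::geom_line() +
    ggplot2::geom_line(ggplot2::aes(y = .data$net_charge_e * scale),
                       linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::scale_y_continuous(
      sec.axis = ggplot2::sec_axis(~ . / scale, name = "net charge (e)")) +
    ggplot2::labs(y = expression(Delta * G / G[0]),
                  title = "pH response") +
    ggplot2::theme_minimal()
}

#' Plot an average-height fit
#'
#' @param object A `height_fit` from [fit_average_height()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot height_fit
#' @export
autoplot.height_fit <- function(object, ...) {
  d <- object$series
  ggplot2::ggplot(d, ggplot2::aes(.data$lambda_D_nm)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$relative_sensitivity)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "steelblue") +
    ggplot2::labs(x = expression(lambda[D] ~ "(nm)"),
                  y = "relative sensitivity",
                  title = sprintf("fitted <l> = %.2f nm", object$l_nm)) +
    ggplot2::theme_minimal()
}

#' Screening factor versus charge distance
#'
#' Plots \eqn{\Gamma(l)} for a set of Debye lengths, illustrating how
#' quickly the contribution of a charge is screened away by the
#' electrolyte.
#'
#' @param params [device_params()].
#' @param lambda_D_nm Debye lengths to draw one curve each for.
#' @param l_max_nm Upper end of the distance axis (nm).
#' @return A ggplot.
#' @importFrom rlang .data
#' @export
plot_screening_factor <- function(params = device_params(),
                                  lambda_D_nm = c(0.5, 2, 10),
                                  l_max_nm = 30) {
  l <- seq(0, l_max_nm, length.out = 301)
  d <- purrr::map(lambda_D_nm, function(ld) {
    p <- params
    p$lambda_D_nm <- ld
    tibble(l_nm = l, gamma = screening_factor(l, p),
           lambda_D = sprintf("%.3g nm", ld))
  })
  d <- dplyr::bind_rows(d)
  ggplot2::ggplot(d, ggplot2::aes(.data$l_nm, .data$gamma,
                                  colour = .data$lambda_D)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance from wire surface l (nm)",
                  y = expression(Gamma(l)),
                  colour = expression(lambda[D])) +
    ggplot2::theme_minimal()
}
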