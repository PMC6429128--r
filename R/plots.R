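#' Plot methods
#'
#' ggplot2 autoplot methods for the package's result objects: the 1/N
#' extrapolation of a boundary-element quantity, a DLS correlogram with its
#' cumulant fit, a persistent contact map, and a net-charge titration
#' curve.
#'
#' @name plots
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname plots
#' @param object result object.
#' @param ... unused.
#' @export
autoplot.hc_extrapolation <- function(object, ...) {
  df <- object$points
  ggplot2::ggplot(df, ggplot2::aes(x = 1 / .data$n_triangles, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         linetype = 2) +
    ggplot2::labs(x = "1 / N triangles", y = "value",
                  title = sprintf("1/N extrapolation (|r| = %.3f)",
                                  abs(object$correlation_r))) +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @export
autoplot.hc_correlogram <- function(object, ...) {
  df <- tibble::tibble(lag = object$lag_times, g1sq = g1_squared(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lag, y = .data$g1sq)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "lag time (s)", y = expression(group("[", g[1](t), "]")^2)) +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @export
autoplot.hc_cumulant <- function(object, ...) {
  df <- tibble::tibble(lag = object$lag_times, g1sq = object$g1sq)
  cf <- stats::coef(object$fit)
  pred <- function(t) {
    y <- cf[[1]] + cf[[2]] * t + cf[[3]] * t^2
    if (length(cf) > 3) y <- y + cf[[4]] * t^3
    exp(2 * y)
  }
  tt <- exp(seq(log(min(df$lag)), log(max(df$lag)), length.out = 200))
  fitdf <- tibble::tibble(lag = tt, g1sq = pred(tt))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lag, y = .data$g1sq)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_line(data = fitdf, colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "lag time (s)", y = expression(group("[", g[1](t), "]")^2),
                  title = sprintf("cumulant fit: Gamma = %.4g 1/s, PDI = %.3f",
                                  object$gamma, object$pdi)) +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @export
autoplot.hc_contact_map <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$residue_b, y = .data$residue_a,
                                   fill = .data$persistence)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(chain_a ~ chain_b, scales = "free", space = "free") +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "residue (side b)", y = "residue (side a)",
                  fill = "presence") +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @param model a [titration_model()].
#' @param from,to pH range.
#' @export
plot_titration_curve <- function(model, from = 0, to = 14) {
  ph <- seq(from, to, by = 0.05)
  df <- tibble::tibble(pH = ph, Z = net_charge_at_pH(model, ph))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pH, y = .data$Z)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(y = "net charge (e)") +
    ggplot2::theme_minimal()
}
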