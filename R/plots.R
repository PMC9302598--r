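#' Plot an ensemble MSD curve
#'
#' Log-log MSD-versus-lag plot with a ribbon of +/- 1 standard error.
#'
#' @param object An `ensemble_msd` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ensemble_msd <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lag_s, y = .data$msd_um2)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$msd_um2 - .data$se_um2,
                   ymax = .data$msd_um2 + .data$se_um2),
      alpha = 0.25, fill = "steelblue") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "lag time (s)", y = expression(MSD ~ (mu * m^2))) +
    ggplot2::theme_minimal()
}

#' Plot an anomalous diffusion fit over its MSD curve
#'
#' @param object An `anomalous_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.anomalous_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$lag_s)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$msd_um2),
                        size = 0.8, colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted_um2), colour = "firebrick") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "lag time (s)", y = expression(MSD ~ (mu * m^2)),
      subtitle = sprintf("D = %.3g um^2/s^alpha, alpha = %.3f (R^2 = %.4f)",
                         object$D, object$alpha, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot a mixture decomposition over the D_app histogram
#'
#' The log10 D_app density with each fitted Gaussian component and their
#' sum overlaid, the standard presentation of fast/slow/fixed population
#' fitting.
#'
#' @param object A `locus_mixture`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.locus_mixture <- function(object, ...) {
  h <- object$histogram
  grid <- seq(min(h$mid) - 0.3, max(h$mid) + 0.3, length.out = 400)
  comp <- object$components
  curves <- purrr::pmap(
    list(comp$component, comp$mean_log10, comp$sd_log10, comp$weight),
    function(lab, mu, s, w) {
      tibble(component = lab, x = grid, density = w * dnorm(grid, mu, s))
    }) |> bind_rows()
  total <- curves |> group_by(.data$x) |>
    summarise(density = sum(.data$density))
  ggplot2::ggplot() +
    ggplot2::geom_col(data = h, ggplot2::aes(x = .data$mid, y = .data$density),
                      width = object$bin_width, fill = "grey85",
                      colour = "grey70") +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(x = .data$x, y = .data$density,
                                    colour = .data$component)) +
    ggplot2::geom_line(data = total,
                       ggplot2::aes(x = .data$x, y = .data$density),
                       colour = "darkgreen", linewidth = 0.8) +
    ggplot2::labs(x = expression(log[10] ~ D[app] ~ (mu * m^2 / s)),
                  y = "density", colour = "population") +
    ggplot2::theme_minimal()
}

#' Bar chart of component fractions across conditions
#'
#' @param comparison Output of [compare_conditions()].
#' @return A ggplot.
#' @export
plot_fractions <- function(comparison) {
  ggplot2::ggplot(comparison,
                  ggplot2::aes(x = .data$condition, y = .data$percent,
                               fill = .data$component)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "population fraction (%)", fill = NULL) +
    ggplot2::theme_minimal()
}
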