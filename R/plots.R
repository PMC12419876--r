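#' Plot a geometry sensitivity sweep
#'
#' Line plot of the positive-to-negative force ratio `fap_fan` against the
#' swept parameter; grid points outside the model's validity regime are drawn
#' hollow.
#'
#' @param object A `ratio_sweep` from [sweep_parameter()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ratio_sweep
#' @export
autoplot.ratio_sweep <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$param_value_um, y = .data$fap_fan)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$valid), size = 2) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                name = "within validity") +
    ggplot2::labs(
      x = sprintf("%s (um)", object$param[1]),
      y = expression(F[ap] / F[an]),
      title = "Directional asymmetry vs attachment geometry"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the beta fit objective
#'
#' Objective value (sum of squared log10 ratio residuals) over the coarse
#' search grid, with the refined optimum marked.
#'
#' @param object A `beta_fit` from [fit_beta()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot beta_fit
#' @export
autoplot.beta_fit <- function(object, ...) {
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(x = .data$beta, y = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$beta_star, linetype = 2,
                        colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(beta == E[p] / E[b]),
                  y = "objective (squared log10 residuals)",
                  title = sprintf("beta* = %.3g", object$beta_star)) +
    ggplot2::theme_minimal()
}

#' Violin plot of force measurements by angle bin
#'
#' Log-scale violin plot of abscission forces per angle bin, one panel per
#' experiment, with the bin medians marked -- the conventional view of the
#' orders-of-magnitude directional differences.
#'
#' @param samples Force table with columns `experiment`, `angle_bin`,
#'   `force_mN`.
#' @return A ggplot object.
#' @export
plot_force_distributions <- function(samples) {
  check_force_table(samples)
  ggplot2::ggplot(samples,
                  ggplot2::aes(x = .data$angle_bin, y = .data$force_mN)) +
    ggplot2::geom_violin(fill = "grey85", colour = "grey60") +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.4, size = 0.7) +
    ggplot2::stat_summary(fun = median, geom = "crossbar", width = 0.5,
                          linewidth = 0.4) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~experiment, scales = "free_x") +
    ggplot2::labs(x = "angle bin", y = "abscission force (mN)") +
    ggplot2::theme_minimal()
}
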