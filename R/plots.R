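#' Plot the maternal-age spline
#'
#' Fitted smoothing spline of recombination-rate residuals against
#' maternal age, with the fitted minimum marked.
#'
#' @param spline A `recomb_spline` from [fit_age_spline()].
#' @return A ggplot object.
#' @export
plot_age_spline <- function(spline) {
  stopifnot(inherits(spline, "recomb_spline"))
  ggplot2::ggplot(spline$grid, ggplot2::aes(x = .data$age,
                                            y = .data$fitted)) +
    ggplot2::geom_line(linewidth = 0.8, colour = "#2c7fb8") +
    ggplot2::geom_vline(xintercept = spline$argmin_age, linetype = 2,
                        colour = "grey40") +
    ggplot2::labs(x = "Maternal age (months)",
                  y = "Recombination rate residual",
                  subtitle = sprintf("Fitted minimum at %.0f months",
                                     spline$argmin_age)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_age_spline
#' @param object A `recomb_spline`.
#' @param ... Unused.
#' @method autoplot recomb_spline
#' @export
autoplot.recomb_spline <- function(object, ...) plot_age_spline(object)

#' Plot age-group means with standard-error bars
#'
#' @param groups Tibble from [group_summary()] over maternal-age groups.
#' @return A ggplot object.
#' @export
plot_age_groups <- function(groups) {
  g <- dplyr::filter(groups, .data$n > 0)
  ggplot2::ggplot(g, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$se,
                                          ymax = .data$mean + .data$se),
                             colour = "#2c7fb8") +
    ggplot2::labs(x = "Maternal age group",
                  y = "Mean residual (+/- SE)") +
    ggplot2::theme_minimal()
}

#' Boxplot of residuals by temperature category
#'
#' @param data Tibble with columns `Y` and a temperature category column.
#' @param category Column name of the category (default `"T1"`).
#' @return A ggplot object.
#' @export
plot_temperature_residuals <- function(data, category = "T1") {
  d <- data[!is.na(data[[category]]), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[category]], y = .data$Y,
                                  fill = .data[[category]])) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(cold = "#74a9cf",
                                          normal = "grey80",
                                          hot = "#fb6a4a")) +
    ggplot2::labs(x = "Temperature condition",
                  y = "Recombination rate residual") +
    ggplot2::theme_minimal()
}
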