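#' Plot posterior coefficient intervals
#'
#' Dot-and-interval plot of the posterior means and 95% intervals of every
#' coefficient of a fitted model.
#'
#' @param object An `nmix_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nmix_fit <- function(object, ...) {
  s <- tidy(object)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "posterior mean and 95% interval (link scale)",
                  y = NULL, title = object$spec$label) +
    ggplot2::theme_minimal()
}

#' Plot a WAIC model comparison
#'
#' @param object An `nmix_model_table` from [select_models()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nmix_model_table <- function(object, ...) {
  tab <- tibble::as_tibble(object) |>
    dplyr::filter(is.finite(.data$WAIC)) |>
    dplyr::mutate(Model = factor(.data$Model, levels = rev(.data$Model)))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$Weight, y = .data$Model)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("Δ %.2f", .data$dWAIC)), hjust = -0.1, size = 3) +
    ggplot2::scale_x_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "WAIC weight", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the per-year Moran's I scan
#'
#' @param object A `moran_scan` from [residual_scan()].
#' @param alpha Significance level drawn as a reference line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.moran_scan <- function(object, alpha = 0.05, ...) {
  tab <- tibble::as_tibble(object)
  ggplot2::ggplot(tab, ggplot2::aes(x = factor(.data$year),
                                    y = .data$p_value)) +
    ggplot2::geom_hline(yintercept = alpha, linetype = 2,
                        colour = "firebrick") +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "year", y = "Moran's I permutation p-value") +
    ggplot2::theme_minimal()
}

#' Map the residual field for one year
#'
#' @param object A `residual_field` from [fitted_values()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.residual_field <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$x, y = .data$y,
                               colour = .data$residual)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_gradient2() +
    ggplot2::coord_equal() +
    ggplot2::facet_wrap(~year) +
    ggplot2::labs(x = "easting (m)", y = "northing (m)") +
    ggplot2::theme_minimal()
}
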