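#' Boxplot of seasonal niche overlap by level and environmental scale
#'
#' @param overlaps results tibble from [seasonal_overlaps()] or
#'   [run_niche_analysis()].
#' @return a ggplot.
#' @export
plot_overlap <- function(overlaps) {
  ggplot2::ggplot(overlaps,
                  ggplot2::aes(x = .data$level, y = .data$D,
                               fill = .data$mode)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "Schoener's D", fill = "scale") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Barplot of niche-tracking proportions
#'
#' @param rates tibble from [tracking_proportion()] with `level`, `mode`
#'   and `tracking_pct`.
#' @return a ggplot.
#' @export
plot_tracking <- function(rates) {
  ggplot2::ggplot(rates,
                  ggplot2::aes(x = .data$level, y = .data$tracking_pct,
                               fill = .data$mode)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "% units tracking", fill = "scale") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Null distribution of a similarity test
#'
#' Histogram of the simulated Schoener's D values with the observed value
#' (solid) and the 95% null quantile (dashed).
#'
#' @param object a [similarity_test()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.similarity_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$D_sim)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$D_obs, linewidth = 1) +
    ggplot2::geom_vline(xintercept = object$q95, linetype = 2) +
    ggplot2::labs(x = "simulated Schoener's D", y = "count") +
    ggplot2::theme_minimal()
}

#' Posterior coefficient plot of a variance-component fit
#'
#' Posterior means with 95% credible intervals for every stored parameter.
#'
#' @param object a `varcomp_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.varcomp_fit <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$mean, y = .data$parameter)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$q2.5,
                                         xmax = .data$q97.5), height = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "posterior mean (95% CrI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Map one layer of a synthetic environment set
#'
#' @param object an `env_set`.
#' @param variable variable name.
#' @param date a date (weather mode) or NULL with `month` (climate mode).
#' @param month climate month 1-12.
#' @param ... unused.
#' @return a ggplot raster of the layer.
#' @export
autoplot.env_set <- function(object, variable = object$variables[1],
                             date = NULL, month = NULL, ...) {
  if (is.null(date) && is.null(month)) month <- 7
  layer <- if (!is.null(date))
    object$weather[[variable]][, , match(as.Date(date), object$dates)]
  else object$climate[[variable]][, , month]
  df <- expand.grid(
    x_km = object$origin[1] + (seq_len(object$nx) - 0.5) * object$cell_km,
    y_km = object$origin[2] + (seq_len(object$ny) - 0.5) * object$cell_km)
  df$value <- as.vector(layer)
  ggplot2::ggplot(df, ggplot2::aes(.data$x_km, .data$y_km,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = variable) +
    ggplot2::theme_minimal()
}
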