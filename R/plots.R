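# ggplot2 autoplot methods for the package's result types.

#' Plot a density curve
#'
#' @param object A [kernel_density()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot density_curve
#' @export
autoplot.density_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$grid, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "log body length", y = "density") +
    ggplot2::theme_minimal()
}

#' Plot a mode analysis
#'
#' Histogram of the analysed values with the selected mixture's weighted
#' component densities and mode locations overlaid.
#'
#' @param object A `mode_analysis`.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mode_analysis
#' @export
autoplot.mode_analysis <- function(object, bins = 40, ...) {
  values <- object$values
  fit <- object$best_fit
  grid <- seq(min(values), max(values), length.out = 400)
  comp <- list_rbind(lapply(seq_len(fit$k), function(j) {
    tibble(component = factor(j), grid = grid,
           density = fit$weights[j] * dnorm(grid, fit$means[j], fit$sds[j]))
  }))
  ggplot2::ggplot(tibble(values = values), ggplot2::aes(x = .data$values)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey80", colour = "grey50") +
    ggplot2::geom_line(data = comp,
                       ggplot2::aes(x = .data$grid, y = .data$density,
                                    colour = .data$component)) +
    ggplot2::geom_vline(xintercept = object$modes, linetype = "dashed") +
    ggplot2::labs(x = "log value", y = "density") +
    ggplot2::theme_minimal()
}

#' Plot a simulated community
#'
#' Abundance spectrum along the niche axis (one spike per surviving
#' species).
#'
#' @param object A `niche_sim`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot niche_sim
#' @export
autoplot.niche_sim <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$N)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$x, yend = 0)) +
    ggplot2::xlim(object$params$axis_range) +
    ggplot2::labs(x = "niche position (log body length)", y = "abundance") +
    ggplot2::theme_minimal()
}

#' Plot pooled pairwise ratios
#'
#' Histogram of the pooled within-sample body-length ratios.
#'
#' @param object A [pool_ratios()] result.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ratio_set
#' @export
autoplot.ratio_set <- function(object, bins = 60, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$ratio)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey40") +
    ggplot2::labs(x = "body length ratio (larger / smaller)", y = "pairs") +
    ggplot2::theme_minimal()
}
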