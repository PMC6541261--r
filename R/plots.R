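#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_errorbar
#'   geom_hline geom_vline facet_wrap labs scale_x_log10 scale_y_log10
#'   theme_bw autoplot
NULL

#' @export
ggplot2::autoplot

#' Mean-variance trend of the logCPM transformation
#'
#' Square-root residual standard deviation against mean log2 count, with
#' the fitted lowess trend that generates the precision weights.
#' @param voom A `core_voom` object.
#' @return A ggplot object.
#' @export
plot_voom_trend <- function(voom) {
  stopifnot(inherits(voom, "core_voom"))
  lib <- voom$lib_size
  fit <- stats::lm.fit(voom$design, t(voom$E))
  df <- nrow(voom$design) - ncol(voom$design)
  pts <- tibble(
    x = voom$amean + mean(log2(lib + 1)) - log2(1e6),
    y = sqrt(sqrt(colSums(as.matrix(fit$residuals)^2) / df)))
  trend <- tibble(x = voom$trend$x, y = voom$trend$y)
  ggplot(pts, aes(x = .data$x, y = .data$y)) +
    geom_point(alpha = 0.3, size = 0.6) +
    geom_line(data = trend, colour = "red") +
    labs(x = "mean log2 count", y = "sqrt(residual sd)",
         title = "mean-variance trend") +
    theme_bw()
}

#' Threshold-selection diagnostics
#'
#' Degree-fit R^2, exponent, clustering/path ratios and data usage across
#' the candidate threshold grid, with the selected threshold marked.
#' @param object A `core_threshold`.
#' @param ... Unused.
#' @export
autoplot.core_threshold <- function(object, ...) {
  rep_long <- object$report |>
    mutate(cc_ratio = .data$mean_cc / .data$cc_rand,
           path_ratio = .data$mean_path / .data$path_rand) |>
    select("threshold", "r_squared", "slope", "cc_ratio", "path_ratio",
           "pct_used") |>
    tidyr::pivot_longer(-"threshold", names_to = "metric")
  p <- ggplot(rep_long, aes(x = .data$threshold, y = .data$value)) +
    geom_line() +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = "correlation threshold", y = NULL) +
    theme_bw()
  if (!is.na(object$threshold)) {
    p <- p + geom_vline(xintercept = object$threshold, colour = "red",
                        linetype = 2)
  }
  p
}

#' Log-log degree distribution with the fitted power law
#' @param object A `core_powerlaw_fit`.
#' @param ... Unused.
#' @export
autoplot.core_powerlaw_fit <- function(object, ...) {
  tab <- table(object$data)
  pts <- tibble(k = as.numeric(names(tab)),
                pk = as.numeric(tab) / sum(tab))
  kk <- seq(object$xmin, max(pts$k))
  tail_frac <- object$n_tail / length(object$data)
  fitted <- tibble(k = kk,
                   pk = tail_frac * kk^(-object$alpha) * object$C)
  ggplot(pts, aes(x = .data$k, y = .data$pk)) +
    geom_point() +
    geom_line(data = fitted, colour = "red") +
    geom_vline(xintercept = object$xmin, linetype = 3) +
    scale_x_log10() + scale_y_log10() +
    labs(x = "degree k", y = "p(k)",
         title = sprintf("alpha = %.2f, xmin = %d", object$alpha,
                         object$xmin)) +
    theme_bw()
}

#' Factor plot of group means with confidence intervals
#'
#' Line graph of mean log2(expression + 1) over days, one line per species,
#' faceted by gene, with the t-based confidence intervals as error bars.
#' @param data A tibble from [factor_plot_data()].
#' @return A ggplot object.
#' @export
plot_factor_data <- function(data) {
  ggplot(data, aes(x = .data$day, y = .data$mean,
                   colour = .data$species, group = .data$species)) +
    geom_line() + geom_point() +
    geom_errorbar(aes(ymin = .data$ci_lo, ymax = .data$ci_hi), width = 0.6) +
    facet_wrap(~gene, scales = "free_y") +
    labs(x = "day", y = "mean log2(expression + 1)") +
    theme_bw()
}
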