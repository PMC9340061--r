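#' @importFrom ggplot2 ggplot aes geom_point geom_errorbarh geom_hline
#'   geom_vline geom_col labs theme_minimal autoplot coord_flip
NULL

#' Plot mean SES.MPD per metric with confidence intervals
#'
#' Point-and-interval display of community-wide structure: one row per
#' metric, mean SES with its 95% interval, the dashed zero line marking the
#' null expectation. Points left of zero indicate convergence, right of zero
#' divergence.
#'
#' @param departure Tibble from [departure_test()].
#' @return A ggplot object.
#' @export
plot_departure <- function(departure) {
  departure$metric <- factor(departure$metric, levels = rev(unique(departure$metric)))
  ggplot(departure, aes(x = .data$mean_ses, y = .data$metric)) +
    geom_vline(xintercept = 0, linetype = "dashed", colour = "grey40") +
    geom_errorbarh(aes(xmin = .data$ci_lower, xmax = .data$ci_upper), height = 0.2) +
    geom_point(aes(colour = .data$direction), size = 2.5) +
    labs(x = "mean SES.MPD (95% CI)", y = NULL, colour = "direction") +
    theme_minimal()
}

#' Plot phylogenetic signal per trait
#'
#' @param signal Tibble from [phylo_signal()].
#' @param alpha Significance threshold for highlighting.
#' @return A ggplot object.
#' @export
plot_signal <- function(signal, alpha = 0.05) {
  signal$significant <- signal$p_value < alpha
  signal$trait <- factor(signal$trait, levels = rev(unique(signal$trait)))
  ggplot(signal, aes(x = .data$K, y = .data$trait, fill = .data$significant)) +
    geom_col(width = 0.7) +
    geom_vline(xintercept = 1, linetype = "dashed", colour = "grey40") +
    labs(x = "Blomberg's K (dashed line: Brownian expectation)", y = NULL,
         fill = sprintf("p < %g", alpha)) +
    theme_minimal()
}

#' @export
autoplot.trait_pca <- function(object, axes = c(1L, 2L), ...) {
  ax <- paste0("PC", axes)
  df <- object$scores
  pct <- 100 * object$proportion_explained[axes]
  ggplot(df, aes(x = .data[[ax[1]]], y = .data[[ax[2]]])) +
    geom_hline(yintercept = 0, colour = "grey80") +
    geom_vline(xintercept = 0, colour = "grey80") +
    geom_point() +
    labs(x = sprintf("%s (%.1f%%)", ax[1], pct[1]),
         y = sprintf("%s (%.1f%%)", ax[2], pct[2])) +
    theme_minimal()
}

#' @export
autoplot.driver_result <- function(object, ...) {
  if (is.null(object$partition)) {
    stop_validation("empty driver model: nothing to plot")
  }
  pt <- as_tibble(object$partition)
  pt$variable <- factor(pt$variable, levels = pt$variable[order(pt$independent_effect)])
  ggplot(pt, aes(x = .data$independent_effect, y = .data$variable)) +
    geom_col(width = 0.7, fill = "steelblue") +
    labs(x = sprintf("independent effect (full-model R² = %.3f)", object$r_squared),
         y = NULL,
         title = sprintf("Drivers of %s", object$response)) +
    theme_minimal()
}
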