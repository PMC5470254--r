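#' Plot methods
#'
#' `autoplot()` methods and `plot_*()` helpers rendering the standard
#' figures of the pipeline with ggplot2.
#'
#' @param object A `redip_classification` or `redip_grouptest`.
#' @param ... Unused.
#' @return A ggplot object.
#' @name redipr-plots
NULL

#' @rdname redipr-plots
#' @export
autoplot.redip_classification <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$class, y = .data$n, fill = .data$class)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "gene trees",
                  title = "Rediploidization classification of gene trees") +
    ggplot2::theme_minimal()
}

#' @rdname redipr-plots
#' @export
autoplot.redip_grouptest <- function(object, ...) {
  df <- tibble(
    class = rep(names(object$groups),
                vapply(object$groups, length, integer(1))),
    r = unlist(object$groups, use.names = FALSE)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$r,
                                   fill = .data$class)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "Pearson r",
                  subtitle = paste0("Wilcoxon P = ",
                                    format(object$p_value, digits = 3))) +
    ggplot2::theme_minimal()
}

#' @rdname redipr-plots
#' @param blocks Block tibble from [segment_regions()].
#' @export
plot_region_blocks <- function(blocks) {
  ggplot2::ggplot(blocks) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start / 1e6, xend = .data$end / 1e6,
                   y = .data$chrom, yend = .data$chrom,
                   colour = .data$class),
      linewidth = 4
    ) +
    ggplot2::labs(x = "position (Mb)", y = NULL, colour = "region class",
                  title = "LORe and AORe regions along chromosomes") +
    ggplot2::theme_minimal()
}

#' @rdname redipr-plots
#' @param windows Window tibble from [window_correlation()].
#' @param threshold Correlation threshold drawn as a reference line.
#' @export
plot_window_correlation <- function(windows, threshold = 0.6) {
  ggplot2::ggplot(windows,
                  ggplot2::aes(x = (.data$window_start + .data$window_end) / 2e6,
                               y = .data$mean_r, colour = .data$high_cor)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::facet_wrap(~chrom) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#c0392b",
                                            `FALSE` = "#2980b9")) +
    ggplot2::labs(x = "window midpoint (Mb)", y = "mean pair correlation",
                  colour = paste0("r >= ", threshold)) +
    ggplot2::theme_minimal()
}
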