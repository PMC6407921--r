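#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' CDF plot for a two-sample comparison
#'
#' Step empirical CDFs of the two groups with the KS statistic and p-value
#' in the subtitle, the standard presentation for target-derepression and
#' occupancy-shift comparisons.
#'
#' @param object A `cdf_comparison` from [cdf_compare()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cdf_comparison
#' @export
autoplot.cdf_comparison <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$ecdf,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "value", y = "cumulative fraction", colour = NULL,
      subtitle = sprintf("Kolmogorov-Smirnov D = %.3f, p = %.3g",
                         object$statistic, object$p_value)) +
    ggplot2::theme_classic()
}

#' Coverage track plot around a gene
#'
#' @param track Coverage tibble from [compute_coverage()].
#' @param gene Optional single-row gene model; when given, the plot is
#'   restricted to the gene span and the 3'UTR is shaded.
#' @return A ggplot object.
#' @export
plot_coverage <- function(track, gene = NULL) {
  df <- track
  p <- ggplot2::ggplot(df)
  if (!is.null(gene)) {
    stopifnot(nrow(gene) == 1L)
    df <- df[df$chrom == gene$chrom & df$strand == gene$strand &
               df$end > gene$span_start & df$start < gene$span_end, ]
    p <- ggplot2::ggplot(df) +
      ggplot2::annotate("rect", xmin = gene$utr3_start, xmax = gene$utr3_end,
                        ymin = -Inf, ymax = Inf, alpha = 0.15)
  }
  p +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                    ymin = 0, ymax = .data$count)) +
    ggplot2::labs(x = "position (nt)", y = "read coverage") +
    ggplot2::theme_classic()
}
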