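# ggplot2 views of the main result types.

#' Histogram of SV cluster cohort frequencies
#'
#' Log10-scaled frequency histogram with the rarity threshold marked, the
#' view used to sanity-check that background common clusters and rare
#' candidate clusters separate.
#'
#' @param clusters Cluster tibble with `cohort_frequency`.
#' @param max_freq Rarity threshold drawn as a vertical line (default 0.01).
#' @return A ggplot object.
#' @export
plot_cluster_frequencies <- function(clusters, max_freq = 0.01) {
  ggplot2::ggplot(clusters, ggplot2::aes(x = .data$cohort_frequency)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey35") +
    ggplot2::geom_vline(xintercept = max_freq, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "cohort carrier frequency (log10)", y = "clusters",
                  title = "SV cluster frequency spectrum") +
    ggplot2::theme_minimal()
}

#' Depth profile around a deletion with the mosaic-fraction estimate
#'
#' @param depth Depth table rows for one sample and chromosome.
#' @param sv One-row data frame with `chrom`, `start`, `end`.
#' @param sample_id Sample to plot.
#' @return A ggplot object.
#' @export
plot_mosaic_depth <- function(depth, sv, sample_id) {
  d <- dplyr::filter(depth, .data$sample_id == .env$sample_id,
                     .data$chrom == sv$chrom)
  est <- estimate_mosaic(depth, sample_id, sv)
  ggplot2::ggplot(d) +
    ggplot2::annotate("rect", xmin = sv$start, xmax = sv$end, ymin = -Inf,
                      ymax = Inf, alpha = 0.15, fill = "firebrick") +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start, xend = .data$end,
                                       y = .data$mean_depth,
                                       yend = .data$mean_depth),
                          linewidth = 1.2) +
    ggplot2::labs(x = sv$chrom, y = "mean depth",
                  title = sprintf("%s: estimated %.0f%% of cells carry the deletion",
                                  sample_id, est$fraction_pct)) +
    ggplot2::theme_minimal()
}

#' ROH regions along a chromosome
#'
#' @param regions ROH tibble (`chrom`, `start`, `end`).
#' @param locus Optional one-row data frame marking a candidate locus.
#' @return A ggplot object.
#' @export
plot_roh <- function(regions, locus = NULL) {
  p <- ggplot2::ggplot(regions) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start / 1e6,
                                       xend = .data$end / 1e6,
                                       y = .data$chrom, yend = .data$chrom),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::labs(x = "position (Mb)", y = NULL,
                  title = "Runs of homozygosity") +
    ggplot2::theme_minimal()
  if (!is.null(locus)) {
    p <- p + ggplot2::annotate("point", x = (locus$start + locus$end) / 2e6,
                               y = locus$chrom, shape = 4, size = 3,
                               colour = "firebrick")
  }
  p
}

#' @export
autoplot.secondhit_screen <- function(object, ...) {
  top <- dplyr::filter(object$candidates, .data$rank <= 3)
  ggplot2::ggplot(top, ggplot2::aes(x = .data$case_id, y = .data$rank_score,
                                    fill = .data$phase)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "evidence score",
                  title = "Top candidate second hits per case",
                  fill = "phase") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
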