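# ggplot2 methods for the main result types.

#' Plot a significance-stability profile
#'
#' Ranks miRNAs by their aggregated stability and overlays the male and
#' female stratified proportions, with a reference line at the
#' significance level (the chance probability of a significant
#' iteration).
#'
#' @param object An `"mb_stability"` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mb_stability <- function(object, ...) {
  wide <- tidyr::pivot_wider(
    dplyr::select(object, "mirna_id", "stratum", "prop_significant"),
    names_from = "stratum", values_from = "prop_significant")
  ord <- wide$mirna_id[order(-wide$aggregated)]
  df <- dplyr::mutate(object,
                      mirna_id = factor(.data$mirna_id, levels = ord))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mirna_id,
                                   y = .data$prop_significant,
                                   colour = .data$stratum)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = attr(object, "alpha") %||% 0.05,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(aggregated = "black",
                                            male = "#3366BB",
                                            female = "#BB3333")) +
    ggplot2::labs(x = NULL, y = "Proportion of significant iterations",
                  colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Forest plot of bootstrap effect sizes
#'
#' Median Hedges' g with its 95% bootstrap percentile interval per
#' miRNA.
#'
#' @param object An `"mb_effect"` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mb_effect <- function(object, ...) {
  df <- dplyr::arrange(object, .data$median_g)
  df$mirna_id <- factor(df$mirna_id, levels = unique(df$mirna_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$median_g,
                                   y = .data$mirna_id)) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Hedges' g (median, 95% percentile CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Histogram of bootstrap significant-correlation counts
#'
#' @param object An `"mb_counts"` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mb_counts <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n_significant)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey30") +
    ggplot2::labs(
      x = "Significant correlations per iteration", y = "Iterations",
      title = sprintf("%s / %s / trimester %s",
                      attr(object, "group") %||% "",
                      attr(object, "stratum") %||% "",
                      attr(object, "time_point") %||% "")) +
    ggplot2::theme_minimal()
}

#' Bar chart of chromosome-pair enrichment
#'
#' @param object An `"mb_enrichment"` tibble.
#' @param k Show the top `k` defined pairs.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mb_enrichment <- function(object, k = 10, ...) {
  df <- top_pairs(object, k = k)
  df$pair <- factor(paste(df$chrom_a, df$chrom_b, sep = "-"),
                    levels = rev(paste(df$chrom_a, df$chrom_b,
                                       sep = "-")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$percent_change,
                                   y = .data$pair)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "Change in significant correlations (%)",
                  y = "Chromosome pair") +
    ggplot2::theme_minimal()
}
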