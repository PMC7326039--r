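#' Plot the genomic-context mix of called junctions
#'
#' Bar chart of junction counts per genomic-origin pair across the
#' back-splice junction (exonic/intronic/intergenic on each side).
#'
#' @param junctions Classified junction tibble from [classify_context()].
#' @return A ggplot object.
#' @export
plot_context_mix <- function(junctions) {
  df <- junctions |> count(.data$context_pair)
  ggplot2::ggplot(df, ggplot2::aes(stats::reorder(.data$context_pair, -.data$n),
                                   .data$n)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "genomic origin pair", y = "circRNA candidates") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot positional bias within the mRNA body
#'
#' Percentage of exonic circRNAs overlapping each mature-mRNA region class.
#'
#' @param bias Tibble from [positional_bias()].
#' @return A ggplot object.
#' @export
plot_positional_bias <- function(bias) {
  ggplot2::ggplot(bias, ggplot2::aes(.data$region, 100 * .data$fraction)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "mRNA region", y = "% of exonic circRNAs overlapping") +
    ggplot2::theme_minimal()
}

#' Volcano-style view of grade-discrimination tests
#'
#' Scatter of each feature's largest between-group mean difference against
#' its BH-adjusted p-value.
#'
#' @param results ANOVA result tibble from [anova_per_feature()].
#' @param alpha Significance threshold to mark.
#' @return A ggplot object.
#' @export
plot_differential <- function(results, alpha = 0.05) {
  mean_cols <- grep("^mean_", names(results), value = TRUE)
  m <- as.matrix(results[, mean_cols])
  df <- results |>
    mutate(spread = apply(m, 1, max) - apply(m, 1, min),
           significant = .data$adjusted_p < alpha)
  ggplot2::ggplot(df, ggplot2::aes(.data$spread, -log10(.data$adjusted_p),
                                   colour = .data$significant)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "max between-grade difference (log2 C/L)",
                  y = "-log10 adjusted p") +
    ggplot2::theme_minimal()
}
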