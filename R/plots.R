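#' Volcano plot of a differential-expression result
#'
#' @param object A `chill_diff` from [diff_expression()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chill_diff <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$log2fc, y = -log10(.data$fdr),
                               colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(up = "#d7301f", down = "#0570b0",
                                            ns = "grey60")) +
    ggplot2::labs(x = "log2 fold change (LT / CK)",
                  y = expression(-log[10] ~ FDR),
                  colour = NULL,
                  title = paste("Differential expression:",
                                attr(object, "level"))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Scatter of RNA vs Ribo fold changes coloured by five-group label
#'
#' @param diff_rna,diff_ribo `chill_diff` results at the two levels.
#' @param groups Tibble `gene_id`, `group`.
#' @return A ggplot object.
#' @export
plot_group_scatter <- function(diff_rna, diff_ribo, groups) {
  df <- tibble(gene_id = diff_rna$gene_id, rna = diff_rna$log2fc) |>
    inner_join(tibble(gene_id = diff_ribo$gene_id,
                      ribo = diff_ribo$log2fc), by = "gene_id") |>
    inner_join(groups, by = "gene_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rna, y = .data$ribo,
                                   colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::labs(x = "log2FC transcription", y = "log2FC translation",
                  colour = "group") +
    ggplot2::theme_minimal()
}

#' Ribosome-footprint length distribution
#'
#' @param rf_lengths Tibble from [rf_length_distribution()].
#' @return A ggplot object.
#' @export
plot_rf_lengths <- function(rf_lengths) {
  ggplot2::ggplot(rf_lengths, ggplot2::aes(x = .data$length, y = .data$n)) +
    ggplot2::geom_col(fill = "#2b8cbe") +
    ggplot2::labs(x = "footprint length (nt)", y = "reads") +
    ggplot2::theme_minimal()
}

#' Genomic distribution of THSs by category
#'
#' @param ann Annotated THS tibble from [annotate_ths()] (or several,
#'   row-bound with a `condition` column).
#' @return A ggplot object.
#' @export
plot_ths_categories <- function(ann) {
  df <- ann |> dplyr::count(.data$category)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$n)) +
    ggplot2::geom_col(fill = "#756bb1") +
    ggplot2::labs(x = NULL, y = "THSs") +
    ggplot2::theme_minimal()
}

#' Density of a uORF feature by translation class
#'
#' @param uorfs uORF tibble with the feature column and logical
#'   `translated`.
#' @param feature Feature column name (default `"length_nt"`).
#' @return A ggplot object.
#' @export
plot_uorf_feature <- function(uorfs, feature = "length_nt") {
  df <- mutate(uorfs, class = if_else(.data$translated, "translated",
                                      "untranslated"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[feature]],
                                   colour = .data$class)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = feature, colour = NULL) +
    ggplot2::theme_minimal()
}
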