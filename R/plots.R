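#' Plot a conservation profile
#'
#' Majority-base fraction per alignment column, with the gap fraction as a
#' secondary trace; conserved primer windows stand out as plateaus near 1.
#'
#' @param object A `conservation_profile`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.conservation_profile <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("column", "majority_fraction",
                                  "gap_fraction")],
    -"column", names_to = "metric", values_to = "fraction")
  ggplot2::ggplot(df, ggplot2::aes(.data$column, .data$fraction,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "alignment column (0-based)", y = "fraction",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a quantification result
#'
#' Corrected percentage per species, labelled with the raw read counts.
#'
#' @param object A `quant_result`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.quant_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$label <- ifelse(is.na(df$name), as.character(df$species_taxid), df$name)
  ggplot2::ggplot(df, ggplot2::aes(.data$label, .data$percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = paste0(.data$raw_reads, " reads")),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "C-value-corrected share (%)") +
    ggplot2::theme_minimal()
}

#' Histogram of predicted amplicon lengths
#'
#' @param amplicons Amplicon tibble from [predict_amplicons()].
#' @param binwidth Histogram bin width in bases (default 5).
#' @return A ggplot object.
#' @export
plot_amplicon_lengths <- function(amplicons, binwidth = 5) {
  ggplot2::ggplot(amplicons,
                  ggplot2::aes(.data$length_with_primers)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey30") +
    ggplot2::labs(x = "amplicon length with primers (bp)", y = "count") +
    ggplot2::theme_minimal()
}
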