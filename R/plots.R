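# ggplot2 front-ends for the main result types.

#' Plot a pile-up matrix as a heatmap
#'
#' @param object A [pileup_matrix()].
#' @param ... Unused.
#' @return A ggplot; masked cells are blank.
#' @export
autoplot.pileup_matrix <- function(object, ...) {
  df <- tidy.pileup_matrix(object)
  df$value[df$masked] <- NA
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$locus,
    fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "white") +
    ggplot2::labs(x = "offset (bp)", y = "locus", fill = "value") +
    ggplot2::theme_minimal()
}

#' Plot a directionality-index track
#'
#' @param object A `di_track` from [directionality_index()].
#' @param ... Unused.
#' @return A ggplot with positive DI above and negative below the axis.
#' @export
autoplot.di_track <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$start, y = .data$DI,
    fill = .data$DI > 0)) +
    ggplot2::geom_col(width = df$end - df$start, show.legend = FALSE) +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#b2182b", `FALSE` = "#2166ac")) +
    ggplot2::labs(x = "position (bp)", y = "directionality index") +
    ggplot2::theme_minimal()
}

#' Plot an enrichment profile with significance tiers
#'
#' @param object An `enrichment_profile` from [zscore_profile()].
#' @param ... Unused.
#' @return A ggplot of the profile with significant bins highlighted.
#' @export
autoplot.enrichment_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$value)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(data = df[df$tier != "ns", , drop = FALSE],
      ggplot2::aes(color = .data$tier)) +
    ggplot2::labs(x = "offset (bp)", y = "value", color = "significance") +
    ggplot2::theme_minimal()
}

#' Volcano-style overview of differential grid cells
#'
#' @param tests A `paired_grid_tests` tibble.
#' @param alpha Significance line (default 0.05).
#' @return A ggplot of delta vs -log10 p, colored by favored condition.
#' @export
plot_differential_cells <- function(tests, alpha = 0.05) {
  df <- tests[!is.na(tests$p), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_delta,
    y = -log10(pmax(.data$p, 1e-300)), color = .data$favored)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::labs(x = "mean delta (condition 2 - condition 1)",
      y = "-log10 p", color = "favored") +
    ggplot2::theme_minimal()
}
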