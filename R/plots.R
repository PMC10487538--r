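#' Plot a reduced-space embedding
#'
#' @param object A `reduced_space`.
#' @param labels Optional named per-cell labels to color by.
#' @param dims Which two retained dimensions to show (default first two).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.reduced_space <- function(object, labels = NULL, dims = c(1, 2), ...) {
  df <- tidy(object)
  dim_cols <- names(df)[-1][dims]
  df$label <- if (is.null(labels)) "cell" else unname(labels[df$cell])
  ggplot2::ggplot(df, ggplot2::aes(.data[[dim_cols[1]]], .data[[dim_cols[2]]],
                                   color = .data$label)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.7) +
    ggplot2::labs(color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot CNV score against correlation with the putative-tumor profile
#'
#' @param calls The `cells` tibble from [classify_malignant()].
#' @return A ggplot colored by malignancy call.
#' @export
plot_cnv_calls <- function(calls) {
  ggplot2::ggplot(calls, ggplot2::aes(.data$cnv_score, .data$cnv_correlation,
                                      color = .data$call)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.7) +
    ggplot2::labs(x = "CNV score (mean squared residual)",
                  y = "Correlation with top-5% profile", color = NULL) +
    ggplot2::theme_minimal()
}

#' Volcano-style view of candidate peak-to-gene links
#'
#' @param links Candidate link tibble from [correlate_peak_gene()].
#' @param r_min,fdr_max Thresholds to mark (defaults 0.45, 1e-12).
#' @return A ggplot of correlation against -log10 FDR.
#' @export
plot_links <- function(links, r_min = 0.45, fdr_max = 1e-12) {
  links$passing <- links$r >= r_min & links$fdr <= fdr_max &
    links$peak_class == "distal"
  ggplot2::ggplot(links, ggplot2::aes(.data$r, -log10(pmax(.data$fdr, 1e-300)),
                                      color = .data$passing)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::geom_vline(xintercept = r_min, linetype = 2) +
    ggplot2::geom_hline(yintercept = -log10(fdr_max), linetype = 2) +
    ggplot2::labs(x = "Pearson r (metacells)", y = "-log10 FDR",
                  color = "passes filter") +
    ggplot2::theme_minimal()
}

#' Bar chart of regulatory load per enhancer set
#'
#' @param load Result of [regulatory_load()].
#' @return A ggplot of mean linked genes per peak for each set.
#' @export
plot_regulatory_load <- function(load) {
  df <- load$summary[is.finite(load$summary$mean_genes_per_peak), , drop = FALSE]
  ggplot2::ggplot(df,
                  ggplot2::aes(.data$set, .data$mean_genes_per_peak,
                               fill = .data$set)) +
    ggplot2::geom_col(width = 0.6, show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "Mean linked genes per peak",
                  subtitle = sprintf("rank-sum p = %.3g", load$p_value)) +
    ggplot2::theme_minimal()
}
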