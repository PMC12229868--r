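#' Forest-style plot of differential-abundance estimates
#'
#' Fold changes with 95% confidence intervals, log2 x-axis, one row per
#' protein whose interval excludes no change (or all proteins when
#' `conclusive_only = FALSE`).
#'
#' @param de_results tibble from [extract_group_contrasts()].
#' @param conclusive_only show only proteins whose CI excludes 0.
#' @return a ggplot object.
#' @export
plot_de_intervals <- function(de_results, conclusive_only = TRUE) {
  df <- de_results
  if (conclusive_only) df <- df[df$direction != "inconclusive", , drop = FALSE]
  df <- df[order(df$delta_log2), , drop = FALSE]
  df$protein <- factor(df$protein, levels = df$protein)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta_log2, y = .data$protein,
                                   colour = .data$direction)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high),
                             size = 0.25) +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b", down = "#2980b9",
                                            inconclusive = "grey60")) +
    ggplot2::labs(x = "log2 fold change (OA vs control)", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal(base_size = 9)
}

#' @exportS3Method ggplot2::autoplot
autoplot.npx_pca <- function(object, ...) {
  ve <- round(100 * object$var_explained[1:2], 1)
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = paste0("PC1 (", ve[1], "%)"),
                  y = paste0("PC2 (", ve[2], "%)"), colour = NULL) +
    ggplot2::theme_minimal()
}

#' Dilution plot for one assay
#'
#' NPX against dilution factor for every sample, with the assay's LOD/ULOQ
#' band — the visual check behind dilution selection and linearity QC.
#'
#' @param npx long NPX table.
#' @param assay_id assay to plot.
#' @return a ggplot object.
#' @export
plot_dilution_series <- function(npx, assay_id) {
  df <- npx[npx$assay_id == assay_id, , drop = FALSE]
  if (!nrow(df)) stop("assay not present: ", assay_id)
  ggplot2::ggplot(df, ggplot2::aes(x = log2(.data$dilution), y = .data$npx,
                                   group = .data$sample_id)) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$lod),
                        linetype = 3, colour = "grey40") +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$uloq),
                        linetype = 3, colour = "grey40") +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(title = assay_id, x = "log2 dilution factor",
                  y = "NPX (log2)") +
    ggplot2::theme_minimal()
}
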