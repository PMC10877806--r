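#' Volcano plot of per-gene FI associations
#'
#' Plots each gene's coefficient against -log10(p), with horizontal guides
#' at the 0.05, 0.01 and 0.001 significance tiers.
#'
#' @param gene_assoc A `gene_assoc` table from [genewise_fi_models()].
#' @param tiers P-value guide lines; default 0.05, 0.01, 0.001.
#' @return A ggplot object.
#' @export
plot_volcano <- function(gene_assoc, tiers = frailomics_defaults$p_tiers) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("plot_volcano requires the ggplot2 package")
  }
  dat <- gene_assoc[!is.na(gene_assoc$p), ]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$beta, y = .data$neg_log10_p)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(tiers), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "expression change per unit FI score",
                  y = expression(-log[10] ~ p)) +
    ggplot2::theme_minimal()
}
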