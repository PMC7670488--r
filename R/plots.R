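#' Manhattan-style plot of a single-variant scan
#'
#' @param object a `variant_scan`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.variant_scan <- function(object, ...) {
  df <- object$results
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = -log10(.data$p_fisher))) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "position", y = expression(-log[10](p)),
                  title = sprintf("Single-variant scan (lambda[gc] = %.3f)",
                                  object$inflation$lambda_gc)) +
    ggplot2::theme_minimal()
}

#' Gene-level scan plot
#'
#' One point per gene, ordered by genome position of its first variant
#' (falling back to table order), with the Bonferroni and suggestive
#' thresholds drawn.
#'
#' @param object a `gene_scan`.
#' @param suggestive_p suggestive line.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.gene_scan <- function(object, suggestive_p = 1e-4, ...) {
  df <- object$results
  df$idx <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$idx, y = -log10(.data$p_chi))) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(object$bonferroni),
                        colour = "red", linetype = 2) +
    ggplot2::geom_hline(yintercept = -log10(suggestive_p),
                        colour = "blue", linetype = 3) +
    ggplot2::labs(x = "gene rank", y = expression(-log[10](P[chi])),
                  title = "Gene-level LOF variant enrichment") +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential-expression result
#'
#' @param object a `de_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.de_result <- function(object, ...) {
  df <- tidy(object)
  thr <- attr(object, "lfc_threshold")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lfc, y = -log10(.data$p),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-thr, thr), linetype = 2) +
    ggplot2::scale_colour_manual(values = c("FALSE" = "grey50",
                                            "TRUE" = "firebrick")) +
    ggplot2::labs(x = expression(log[2] ~ "fold change (B vs A)"),
                  y = expression(-log[10](p)), colour = "significant") +
    ggplot2::theme_minimal()
}

#' PCA scatter plot
#'
#' @param object a `pca_genotypes`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.pca_genotypes <- function(object, ...) {
  pve <- 100 * object$eigenvalues / sum(object$eigenvalues)
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               colour = .data$cohort)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", pve[1]),
                  y = sprintf("PC2 (%.1f%%)", pve[2])) +
    ggplot2::theme_minimal()
}
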