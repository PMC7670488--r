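#' Tidy a single-variant scan
#'
#' @param x a `variant_scan` from [run_single_variant_scan()].
#' @param ... unused.
#' @return the per-variant results tibble.
#' @export
tidy.variant_scan <- function(x, ...) x$results

#' @rdname tidy.variant_scan
#' @export
glance.variant_scan <- function(x, ...) {
  tibble(lambda_gc = x$inflation$lambda_gc, n_tests = x$inflation$n_tests)
}

#' Tidy a gene-level scan
#'
#' @param x a `gene_scan` from [run_gene_scan()].
#' @param ... unused.
#' @return the per-gene results tibble.
#' @export
tidy.gene_scan <- function(x, ...) x$results

#' @rdname tidy.gene_scan
#' @export
glance.gene_scan <- function(x, ...) {
  tibble(
    n_genes = nrow(x$results),
    lambda_gc = if (is.null(x$inflation)) NA_real_ else x$inflation$lambda_gc,
    bonferroni = x$bonferroni,
    n_significant = sum(x$results$significant_bonferroni, na.rm = TRUE),
    n_suggestive = sum(x$results$suggestive, na.rm = TRUE)
  )
}

#' Tidy a differential-expression result
#'
#' @param x a `de_result` from [run_de()]/[call_degs()].
#' @param ... unused.
#' @return the per-gene tibble (classes stripped).
#' @export
tidy.de_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "de_result")
  as_tibble(out)
}

#' @rdname tidy.de_result
#' @export
glance.de_result <- function(x, ...) {
  prior <- attr(x, "prior")
  tibble(
    n_genes = nrow(x),
    lfc_threshold = attr(x, "lfc_threshold"),
    d0 = if (is.null(prior)) NA_real_ else prior$d0,
    s0_sq = if (is.null(prior)) NA_real_ else prior$s0_sq,
    n_up = attr(x, "n_up"), n_down = attr(x, "n_down"),
    n_up_fdr = attr(x, "n_up_fdr"), n_down_fdr = attr(x, "n_down_fdr")
  )
}

#' Tidy a genotype PCA
#'
#' @param x a `pca_genotypes` result.
#' @param ... unused.
#' @return the per-sample score tibble.
#' @export
tidy.pca_genotypes <- function(x, ...) x$scores

#' @rdname tidy.pca_genotypes
#' @export
glance.pca_genotypes <- function(x, ...) {
  tibble(n_variants_used = x$n_variants_used,
         pve_pc1 = x$eigenvalues[1] / sum(x$eigenvalues),
         pve_pc2 = x$eigenvalues[2] / sum(x$eigenvalues))
}
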