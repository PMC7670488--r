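#' Expression table
#'
#' Gene-by-sample expression container: a value matrix (read counts or
#' TPM, flagged by `unit`), per-gene effective lengths, and the sample
#' sheet with cohort labels.
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param genes tibble with columns `gene_id`, `length` (bp, > 0).
#' @param samples tibble with columns `sample_id`, `cohort`.
#' @param unit `"counts"` or `"tpm"`.
#' @return an object of class `expression_table`.
#' @export
expression_table <- function(values, genes, samples, unit = c("counts", "tpm")) {
  unit <- arg_match(unit)
  values <- as.matrix(values)
  genes <- as_tibble(genes)
  samples <- as_tibble(samples)
  stopifnot(
    nrow(values) == nrow(genes), ncol(values) == nrow(samples),
    all(c("gene_id", "length") %in% names(genes)),
    all(c("sample_id", "cohort") %in% names(samples))
  )
  if (any(genes$length <= 0)) abort("gene lengths must be positive")
  if (any(values < 0, na.rm = TRUE)) abort("expression values must be >= 0")
  if (unit == "tpm") {
    sums <- colSums(values)
    if (any(abs(sums - 1e6) > 1e-3)) {
      abort("TPM columns must each sum to 1e6 (tolerance 1e-3)")
    }
  }
  dimnames(values) <- list(genes$gene_id, samples$sample_id)
  structure(list(values = values, genes = genes, samples = samples, unit = unit),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("<expression_table> %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values), x$unit))
  invisible(x)
}

#' Convert read counts to TPM
#'
#' Transcripts per million: per sample, each gene's count is divided by
#' its effective length (per-kilobase rate) and rates are rescaled so the
#' column sums to 1e6.
#'
#' @param counts numeric matrix (genes x samples) of non-negative counts.
#' @param lengths per-gene effective lengths (bp).
#' @return numeric matrix of TPM values, columns summing to 1e6.
#' @export
tpm_from_counts <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (length(lengths) != nrow(counts)) {
    abort("one length per gene is required")
  }
  if (any(lengths <= 0)) abort("gene lengths must be positive")
  if (any(counts < 0)) abort("counts must be non-negative")
  rate <- counts / lengths
  sums <- colSums(rate)
  zero <- sums == 0
  if (any(zero)) {
    abort(paste0("sample(s) with all-zero counts: ",
                 paste(colnames(counts)[zero], collapse = ", ")))
  }
  sweep(rate, 2, sums, "/") * 1e6
}

#' Convert an expression table to TPM
#'
#' @param expr an [expression_table()].
#' @return an `expression_table` with `unit = "tpm"` (unchanged if
#'   already TPM).
#' @export
as_tpm <- function(expr) {
  stopifnot(inherits(expr, "expression_table"))
  if (expr$unit == "tpm") return(expr)
  expression_table(tpm_from_counts(expr$values, expr$genes$length),
                   expr$genes, expr$samples, unit = "tpm")
}
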