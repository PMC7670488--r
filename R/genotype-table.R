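#' Genotype table
#'
#' The central genotype container: a samples-by-variants matrix of
#' minor-allele dosages (0/1/2, `NA` for missing calls) together with a
#' sample sheet (id, cohort) and a variant sheet (position, alleles, gene
#' assignment, functional class).  Dosages are oriented once, on the
#' combined sample, so that the counted allele is the globally rarer one;
#' a frequency tie at exactly 0.5 orients to ALT.
#'
#' @param dosage integer matrix, samples in rows, variants in columns.
#'   Entries must be 0, 1, 2 or `NA`.
#' @param samples tibble with columns `sample_id`, `cohort` (labels
#'   `"A"`/`"B"`).
#' @param variants tibble with columns `variant_id`, `chrom`, `pos`
#'   (1-based), `ref`, `alt`, `gene` (`NA` when unassigned or ambiguous),
#'   `func_class`, and logical `flipped` (`TRUE` when the counted minor
#'   allele is REF rather than ALT).
#' @param ledger optional QC ledger tibble carried along with the table
#'   (see [qc_ledger()]).
#'
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(dosage, samples, variants, ledger = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  samples <- as_tibble(samples)
  variants <- as_tibble(variants)
  stopifnot(
    nrow(dosage) == nrow(samples),
    ncol(dosage) == nrow(variants),
    all(c("sample_id", "cohort") %in% names(samples)),
    all(c("variant_id", "chrom", "pos", "ref", "alt", "gene", "func_class") %in%
          names(variants))
  )
  if (!all(samples$cohort %in% c("A", "B"))) {
    abort("cohort labels must be 'A' or 'B'")
  }
  if (anyDuplicated(samples$sample_id)) abort("duplicated sample ids")
  if (anyDuplicated(variants$variant_id)) abort("duplicated variant ids")
  bad <- !(dosage %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) abort("dosage entries must be 0, 1, 2 or NA")
  if (any(variants$pos < 1L)) abort("positions must be 1-based (>= 1)")
  if (is.null(variants[["flipped"]])) variants$flipped <- FALSE
  dimnames(dosage) <- list(samples$sample_id, variants$variant_id)
  structure(
    list(dosage = dosage, samples = samples, variants = variants,
         ledger = ledger),
    class = "genotype_table"
  )
}

#' @export
print.genotype_table <- function(x, ...) {
  n_a <- sum(x$samples$cohort == "A")
  n_b <- sum(x$samples$cohort == "B")
  cat(sprintf(
    "<genotype_table> %d samples (A: %d, B: %d) x %d variants\n",
    nrow(x$dosage), n_a, n_b, ncol(x$dosage)
  ))
  n_gene <- sum(!is.na(x$variants$gene))
  cat(sprintf("  %d variants with a gene assignment; missing call rate %.3f\n",
              n_gene, mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$dosage)

#' Number of samples and variants
#' @param gt a [genotype_table()]
#' @return integer count.
#' @export
n_samples <- function(gt) nrow(gt$dosage)

#' @rdname n_samples
#' @export
n_variants <- function(gt) ncol(gt$dosage)

#' Subset a genotype table
#'
#' @param gt a [genotype_table()]
#' @param variants logical/integer/character index of variants to keep.
#' @param samples logical/integer/character index of samples to keep.
#' @return a `genotype_table`.
#' @export
subset_genotypes <- function(gt, variants = NULL, samples = NULL) {
  v_idx <- if (is.null(variants)) seq_len(n_variants(gt)) else variants
  s_idx <- if (is.null(samples)) seq_len(n_samples(gt)) else samples
  if (is.character(v_idx)) v_idx <- match(v_idx, gt$variants$variant_id)
  if (is.character(s_idx)) s_idx <- match(s_idx, gt$samples$sample_id)
  genotype_table(
    gt$dosage[s_idx, v_idx, drop = FALSE],
    gt$samples[s_idx, , drop = FALSE],
    gt$variants[v_idx, , drop = FALSE],
    ledger = gt$ledger
  )
}

#' Per-variant summaries
#'
#' Call rate, minor allele frequency (on the combined sample, of the
#' counted allele) and per-cohort genotype counts.
#'
#' @param gt a [genotype_table()]
#' @return tibble with one row per variant: `variant_id`, `call_rate`,
#'   `maf`, and genotype counts `n0_a`, `n1_a`, `n2_a`, `n0_b`, `n1_b`,
#'   `n2_b`.
#' @export
variant_stats <- function(gt) {
  d <- gt$dosage
  a <- gt$samples$cohort == "A"
  cnt <- function(m, val) colSums(m == val, na.rm = TRUE)
  n_called <- colSums(!is.na(d))
  tibble(
    variant_id = gt$variants$variant_id,
    call_rate = n_called / nrow(d),
    maf = ifelse(n_called > 0, colSums(d, na.rm = TRUE) / (2 * n_called), NA_real_),
    n0_a = cnt(d[a, , drop = FALSE], 0L),
    n1_a = cnt(d[a, , drop = FALSE], 1L),
    n2_a = cnt(d[a, , drop = FALSE], 2L),
    n0_b = cnt(d[!a, , drop = FALSE], 0L),
    n1_b = cnt(d[!a, , drop = FALSE], 1L),
    n2_b = cnt(d[!a, , drop = FALSE], 2L)
  )
}

# Orient a raw ALT-dosage matrix to minor-allele dosage on the combined
# sample; ties (frequency exactly 0.5) stay ALT-oriented.
orient_to_minor <- function(alt_dosage) {
  n_called <- colSums(!is.na(alt_dosage))
  freq <- colSums(alt_dosage, na.rm = TRUE) / (2 * pmax(n_called, 1L))
  flip <- freq > 0.5
  out <- alt_dosage
  out[, flip] <- 2L - alt_dosage[, flip, drop = FALSE]
  list(dosage = out, flipped = flip)
}

# Recover the raw ALT-oriented dosage (for VCF output).
alt_dosage <- function(gt) {
  d <- gt$dosage
  flip <- gt$variants$flipped
  d[, flip] <- 2L - d[, flip, drop = FALSE]
  d
}
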