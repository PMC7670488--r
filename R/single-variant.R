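#' Allelic 2x2 cross-tabulation for one variant
#'
#' Counts minor and major alleles per cohort, excluding missing
#' genotypes from the denominators: `a` is the cohort-A minor-allele
#' count, `b = 2 * n_called_A - a`, and likewise `c`, `d` for cohort B.
#'
#' @param dosages_a,dosages_b dosage vectors (0/1/2, `NA` missing).
#' @return named numeric vector `c(a, b, c, d)`.
#' @export
allelic_crosstab <- function(dosages_a, dosages_b) {
  ok_a <- !is.na(dosages_a)
  ok_b <- !is.na(dosages_b)
  if (!any(ok_a) || !any(ok_b)) abort("a cohort has no called genotypes")
  stopifnot(all(dosages_a[ok_a] %in% 0:2), all(dosages_b[ok_b] %in% 0:2))
  a <- sum(dosages_a[ok_a])
  c_ <- sum(dosages_b[ok_b])
  c(a = a, b = 2 * sum(ok_a) - a, c = c_, d = 2 * sum(ok_b) - c_)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Sums the conditional hypergeometric probabilities of every table with
#' the observed margins whose probability is at most that of the
#' observed table (with relative tolerance 1e-7 on the comparison), the
#' convention of the classical two-sided exact test.
#'
#' @param a,b,c,d non-negative cell counts (rows = cohorts, columns =
#'   minor/major allele).
#' @return two-sided p-value.
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  m1 <- a + b
  m2 <- c + d
  k <- a + c
  if (m1 == 0 || m2 == 0 || k == 0 || b + d == 0) {
    warn("degenerate 2x2 table (zero margin); p = 1")
    return(1)
  }
  support <- max(0, k - m2):min(k, m1)
  probs <- stats::dhyper(support, m1, m2, k)
  p_obs <- probs[match(a, support)]
  min(sum(probs[probs <= p_obs * (1 + 1e-7)]), 1)
}

#' Genomic-control inflation factor
#'
#' Converts each p-value to its 1-df chi-squared quantile and divides
#' the median by 0.4549364, the null median of a chi-squared(1)
#' distribution.
#'
#' @param p_values p-values in (0, 1].
#' @return list of class `inflation_estimate` with `lambda_gc` and
#'   `n_tests`.
#' @export
genomic_inflation <- function(p_values) {
  p_values <- p_values[!is.na(p_values)]
  if (length(p_values) == 0) abort("no p-values supplied")
  if (any(p_values <= 0 | p_values > 1)) abort("p-values must lie in (0, 1]")
  q <- qchisq(p_values, df = 1, lower.tail = FALSE)
  lambda <- median(q) / qchisq(0.5, df = 1, lower.tail = FALSE)
  if (lambda <= 0) {
    warn("median chi-squared is zero (over half the p-values are 1); lambda_gc is degenerate")
  }
  structure(
    list(lambda_gc = lambda, n_tests = length(p_values)),
    class = "inflation_estimate"
  )
}

#' @export
print.inflation_estimate <- function(x, ...) {
  cat(sprintf("<inflation_estimate> lambda_gc = %.4f over %d tests\n",
              x$lambda_gc, x$n_tests))
  invisible(x)
}

#' Single-variant allelic association scan
#'
#' Per variant, builds the allelic 2x2 table and runs the two-sided
#' Fisher exact test; the genomic-control lambda is computed over all
#' tests.  With `gc_correct = TRUE`, a `p_gc` column re-converts each
#' chi-squared quantile divided by lambda back to a p-value.  With a
#' single variant, lambda is computed from that one test (and is
#' statistically meaningless; a median of one value).
#'
#' @param gt a QC'd [genotype_table()].
#' @param gc_correct add a genomic-control-corrected p column.
#' @return object of class `variant_scan`: list with `results` (tibble
#'   sorted by position: `variant_id`, `chrom`, `pos`, `a`, `b`, `c`,
#'   `d`, `p_fisher`, optionally `p_gc`) and `inflation`.
#' @export
run_single_variant_scan <- function(gt, gc_correct = FALSE) {
  if (n_variants(gt) == 0) abort("no variants to scan")
  is_a <- gt$samples$cohort == "A"
  tabs <- t(vapply(seq_len(n_variants(gt)), function(j) {
    allelic_crosstab(gt$dosage[is_a, j], gt$dosage[!is_a, j])
  }, numeric(4)))
  p <- vapply(seq_len(nrow(tabs)), function(i) {
    fisher_exact_two_sided(tabs[i, 1], tabs[i, 2], tabs[i, 3], tabs[i, 4])
  }, numeric(1))
  res <- tibble(
    variant_id = gt$variants$variant_id,
    chrom = gt$variants$chrom, pos = gt$variants$pos,
    a = tabs[, 1], b = tabs[, 2], c = tabs[, 3], d = tabs[, 4],
    p_fisher = p
  )
  infl <- genomic_inflation(res$p_fisher)
  if (gc_correct) {
    chi <- qchisq(res$p_fisher, 1, lower.tail = FALSE) / infl$lambda_gc
    res$p_gc <- pmin(pmax(pchisq(chi, 1, lower.tail = FALSE), 1e-300), 1)
  }
  res <- arrange(res, .data$chrom, .data$pos)
  structure(list(results = res, inflation = infl), class = "variant_scan")
}

#' @export
print.variant_scan <- function(x, ...) {
  cat(sprintf("<variant_scan> %d variants, lambda_gc = %.4f\n",
              nrow(x$results), x$inflation$lambda_gc))
  print(head(x$results, 5))
  invisible(x)
}
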