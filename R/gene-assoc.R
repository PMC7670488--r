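#' Collapsed allele-count cross-tabulation for a gene
#'
#' Sums minor- and major-allele counts over a gene's variants, split by
#' cohort: `A1` is the cohort-A minor-allele count over all non-missing
#' genotypes of the gene's variants, `A2` the corresponding major-allele
#' count, and likewise `B1`, `B2` for cohort B.  With no missingness,
#' `A1 + A2 = 2 * n_per_cohort * n_markers`.
#'
#' @param gt a [genotype_table()].
#' @param variant_ids the gene's variant ids.
#' @return named numeric vector `c(A1, A2, B1, B2)`.
#' @export
gene_crosstab <- function(gt, variant_ids) {
  idx <- match(variant_ids, gt$variants$variant_id)
  if (anyNA(idx)) abort("variant ids missing from genotype table")
  d <- gt$dosage[, idx, drop = FALSE]
  if (all(is.na(d))) abort("all genotypes missing for this gene")
  is_a <- gt$samples$cohort == "A"
  da <- d[is_a, , drop = FALSE]
  db <- d[!is_a, , drop = FALSE]
  a1 <- sum(da, na.rm = TRUE)
  b1 <- sum(db, na.rm = TRUE)
  c(A1 = a1, A2 = 2 * sum(!is.na(da)) - a1,
    B1 = b1, B2 = 2 * sum(!is.na(db)) - b1)
}

#' Pearson chi-squared test for a 2x2 table
#'
#' The closed form
#' `X^2 = N (A1 B2 - A2 B1)^2 / ((A1+A2)(B1+B2)(A1+B1)(A2+B2))` with a
#' 1-df upper-tail p-value.  No continuity correction by default;
#' `correct = TRUE` applies the Yates correction.
#'
#' @param a1,a2,b1,b2 cell counts (cohort A minor/major, cohort B
#'   minor/major).
#' @param correct apply the Yates continuity correction.
#' @return list with `statistic` and `p`.
#' @export
pearson_chi2 <- function(a1, a2, b1, b2, correct = FALSE) {
  stopifnot(a1 >= 0, a2 >= 0, b1 >= 0, b2 >= 0)
  n <- a1 + a2 + b1 + b2
  if (n <= 0) abort("empty table")
  margins <- c(a1 + a2, b1 + b2, a1 + b1, a2 + b2)
  if (any(margins == 0)) {
    warn("zero margin; statistic 0, p = 1")
    return(list(statistic = 0, p = 1))
  }
  num <- abs(a1 * b2 - a2 * b1)
  if (correct) num <- max(num - n / 2, 0)
  stat <- n * num^2 / prod(margins)
  list(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Odds ratio with Woolf confidence interval
#'
#' `OR = (A1 * B2) / (A2 * B1)` with the log-normal (Woolf) interval
#' `exp(log(OR) +/- z * sqrt(1/A1 + 1/A2 + 1/B1 + 1/B2))`.  Any zero
#' cell yields the Null convention: all three fields `NA` and
#' `null = TRUE` (no Haldane-Anscombe correction is applied).
#'
#' @inheritParams pearson_chi2
#' @param z_crit normal quantile for the interval (default two-sided
#'   95%: 1.959964).
#' @return tibble with columns `or`, `ci_low`, `ci_high`, `null`.
#' @export
odds_ratio_woolf <- function(a1, a2, b1, b2, z_crit = 1.959964) {
  if (any(c(a1, a2, b1, b2) == 0)) {
    return(tibble(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                  null = TRUE))
  }
  or <- (a1 * b2) / (a2 * b1)
  se <- sqrt(1 / a1 + 1 / a2 + 1 / b1 + 1 / b2)
  tibble(or = or,
         ci_low = exp(log(or) - z_crit * se),
         ci_high = exp(log(or) + z_crit * se),
         null = FALSE)
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate.
#' @param n_genes number of tests.
#' @return `alpha / n_genes`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_genes) {
  stopifnot(n_genes >= 1, alpha > 0, alpha <= 1)
  alpha / n_genes
}

#' Gene-level LOF association scan
#'
#' For every gene set, builds the collapsed cross-tabulation and runs
#' the requested tests: the collapsed-count Pearson chi-squared with
#' odds ratio and Woolf interval, and the Burden, SKAT and SKAT-O score
#' tests on the per-variant dosage matrix under the intercept-only
#' binary null with Beta(1, 25) MAF weights.  The genomic-control lambda
#' is computed on the chi-squared p-value column; the Bonferroni flag
#' uses `alpha` over the number of genes tested, and a suggestive flag
#' marks `p_chi < suggestive_p`.
#'
#' @param gt a [genotype_table()].
#' @param gene_sets tibble from [select_lof_gene_sets()].
#' @param alpha family-wise significance level.
#' @param suggestive_p suggestive-evidence threshold on `p_chi`.
#' @param tests subset of `c("chi2", "burden", "skat", "skato")` to run.
#' @return object of class `gene_scan`: list with `results` (one row per
#'   gene, sorted by `p_chi`), `inflation`, `bonferroni` and `alpha`.
#'   Per-gene test failures are recorded as `NA` p-values and the scan
#'   continues.
#' @export
run_gene_scan <- function(gt, gene_sets, alpha = 0.05, suggestive_p = 1e-4,
                          tests = c("chi2", "burden", "skat", "skato")) {
  stopifnot(nrow(gene_sets) >= 1)
  tests <- match.arg(tests, several.ok = TRUE)
  y <- as.integer(gt$samples$cohort == "B")
  null <- skat_null_model(y)

  rows <- lapply(seq_len(nrow(gene_sets)), function(i) {
    vids <- gene_sets$variant_ids[[i]]
    out <- tibble(gene = gene_sets$gene[i],
                  n_markers = gene_sets$n_markers[i],
                  A1 = NA_real_, A2 = NA_real_, B1 = NA_real_, B2 = NA_real_,
                  or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                  or_null = NA,
                  p_chi = NA_real_, p_burden = NA_real_, p_skat = NA_real_,
                  p_skato = NA_real_)
    tryCatch({
      ct <- gene_crosstab(gt, vids)
      out$A1 <- ct["A1"]; out$A2 <- ct["A2"]
      out$B1 <- ct["B1"]; out$B2 <- ct["B2"]
      if ("chi2" %in% tests) {
        out$p_chi <- pearson_chi2(ct["A1"], ct["A2"], ct["B1"], ct["B2"])$p
        orci <- odds_ratio_woolf(ct["A1"], ct["A2"], ct["B1"], ct["B2"])
        out$or <- orci$or; out$ci_low <- orci$ci_low
        out$ci_high <- orci$ci_high; out$or_null <- orci$null
      }
      if (any(c("burden", "skat", "skato") %in% tests)) {
        idx <- match(vids, gt$variants$variant_id)
        G <- impute_dosage(gt$dosage[, idx, drop = FALSE])
        w <- default_weights(G)
        if ("burden" %in% tests) {
          out$p_burden <- suppressWarnings(burden_test(G, null, w))
        }
        if ("skat" %in% tests) out$p_skat <- skat_test(G, null, w)
        if ("skato" %in% tests) out$p_skato <- skato_test(G, null, w)
      }
      NULL
    }, error = function(e) NULL)
    out
  })
  res <- bind_rows(rows)
  bonf <- bonferroni_threshold(alpha, nrow(res))
  res$significant_bonferroni <- !is.na(res$p_chi) & res$p_chi < bonf
  res$suggestive <- !is.na(res$p_chi) & res$p_chi < suggestive_p &
    !res$significant_bonferroni
  res <- arrange(res, .data$p_chi)
  infl <- if (any(!is.na(res$p_chi))) {
    genomic_inflation(res$p_chi[!is.na(res$p_chi)])
  } else NULL
  structure(list(results = res, inflation = infl, bonferroni = bonf,
                 alpha = alpha),
            class = "gene_scan")
}

#' @export
print.gene_scan <- function(x, ...) {
  cat(sprintf(
    "<gene_scan> %d genes; Bonferroni threshold %.3g; lambda_gc = %s\n",
    nrow(x$results), x$bonferroni,
    if (is.null(x$inflation)) "NA" else sprintf("%.4f", x$inflation$lambda_gc)
  ))
  print(head(x$results, 5))
  invisible(x)
}
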