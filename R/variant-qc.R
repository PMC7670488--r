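#' QC ledger
#'
#' An auditable record of a filter cascade: one row per filter with the
#' number of variants entering, removed and surviving.  Counts telescope
#' (the survivors of step *k* are the input of step *k + 1*).
#'
#' @param filter filter name(s).
#' @param n_in variants entering the step.
#' @param n_removed variants removed by the step.
#' @return tibble with columns `filter`, `n_in`, `n_removed`, `n_out`.
#' @export
qc_ledger <- function(filter, n_in, n_removed) {
  tibble(filter = filter, n_in = as.integer(n_in),
         n_removed = as.integer(n_removed),
         n_out = as.integer(n_in - n_removed))
}

append_ledger <- function(ledger, filter, n_in, n_removed) {
  bind_rows(ledger, qc_ledger(filter, n_in, n_removed))
}

#' Exact test of Hardy-Weinberg proportions
#'
#' Conditions on the observed allele counts and enumerates every
#' attainable heterozygote count; the two-sided p-value is the total
#' probability of configurations no more probable than the observed one.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts.
#' @return exact two-sided p-value.
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  stopifnot(n_hom_ref >= 0, n_het >= 0, n_hom_alt >= 0)
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0) abort("empty cohort: no genotypes to test")
  n_minor <- min(2 * n_hom_ref + n_het, 2 * n_hom_alt + n_het)
  if (n_minor == 0) return(1)
  hets <- seq(n_minor %% 2, min(n_minor, 2 * n - n_minor), by = 2)
  # P(het = h | allele counts) up to a constant:
  # n! 2^h / (hom_minor! h! hom_major!)
  logp <- lfactorial(n) + hets * log(2) -
    lfactorial((n_minor - hets) / 2) - lfactorial(hets) -
    lfactorial(n - (n_minor + hets) / 2)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[match(n_het, hets)]
  if (is.na(p_obs)) abort("observed heterozygote count incompatible with allele counts")
  sum(p[p <= p_obs * (1 + 1e-12)])
}

#' Apply the variant QC cascade
#'
#' Keeps variants with call rate above `call_rate_min` (strict),
#' combined-sample MAF at least `maf_min`, and not failing the exact
#' Hardy-Weinberg test at `hwe_alpha` in both cohorts (`hwe_rule =
#' "both"`, the default) or in either cohort (`"either"`).
#'
#' @param gt a [genotype_table()].
#' @param call_rate_min call-rate threshold (kept iff call rate is
#'   strictly greater).
#' @param maf_min minimum combined minor allele frequency (kept iff
#'   `maf >= maf_min`).
#' @param hwe_alpha Hardy-Weinberg significance cutoff.
#' @param hwe_rule whether a variant must fail HWE in `"both"` cohorts or
#'   `"either"` cohort to be removed.
#' @return list with elements `genotypes` (filtered table) and `ledger`
#'   (a [qc_ledger()] with one row per filter).
#' @export
apply_variant_qc <- function(gt, call_rate_min = 0.90, maf_min = 0.01,
                             hwe_alpha = 5e-8,
                             hwe_rule = c("both", "either")) {
  hwe_rule <- arg_match(hwe_rule)
  if (!all(c("A", "B") %in% gt$samples$cohort)) abort("both cohorts must be non-empty")
  ledger <- qc_ledger(character(), integer(), integer())

  st <- variant_stats(gt)
  keep <- st$call_rate > call_rate_min
  ledger <- append_ledger(ledger, "call_rate", nrow(st), sum(!keep))
  gt <- subset_genotypes(gt, variants = keep)

  st <- variant_stats(gt)
  keep <- !is.na(st$maf) & st$maf >= maf_min
  ledger <- append_ledger(ledger, "maf", nrow(st), sum(!keep))
  gt <- subset_genotypes(gt, variants = keep)

  st <- variant_stats(gt)
  hwe_p <- function(n0, n1, n2) {
    # few distinct count triples at small n: compute each once
    key <- paste(n0, n1, n2)
    uk <- !duplicated(key)
    pu <- vapply(which(uk), function(i) {
      if (n0[i] + n1[i] + n2[i] == 0) return(1)
      hwe_exact_test(n0[i], n1[i], n2[i])
    }, numeric(1))
    unname(pu[match(key, key[uk])])
  }
  fail_a <- hwe_p(st$n0_a, st$n1_a, st$n2_a) < hwe_alpha
  fail_b <- hwe_p(st$n0_b, st$n1_b, st$n2_b) < hwe_alpha
  fail <- if (hwe_rule == "both") fail_a & fail_b else fail_a | fail_b
  ledger <- append_ledger(ledger, paste0("hwe_", hwe_rule), nrow(st), sum(fail))
  gt <- subset_genotypes(gt, variants = !fail)

  gt$ledger <- bind_rows(gt$ledger, ledger)
  list(genotypes = gt, ledger = ledger)
}

#' Loss-of-function variant classes
#'
#' The seven ANNOVAR-style functional classes treated as
#' loss-of-function for gene-level testing: frameshift and
#' non-frameshift insertions/deletions, nonsynonymous SNVs, stop gains
#' and stop losses.
#'
#' @return character vector of class labels.
#' @export
lof_classes <- function() {
  c("frameshift insertion", "frameshift deletion",
    "nonframeshift insertion", "nonframeshift deletion",
    "nonsynonymous SNV", "stopgain", "stoploss")
}

#' Select per-gene LOF variant sets
#'
#' Keeps variants whose functional class is one of [lof_classes()], with
#' call rate strictly above `call_rate_min`, mapped to exactly one gene
#' (variants flagged as annotated to multiple genes are excluded and
#' logged); genes with at least `min_lof_per_gene` such variants are
#' returned.
#'
#' @param gt a [genotype_table()].
#' @param call_rate_min call-rate threshold (strict).
#' @param min_lof_per_gene minimum LOF variants per retained gene.
#' @return tibble with one row per retained gene: `gene`, `n_markers`,
#'   and a list-column `variant_ids`.  Attribute `excluded_multi_gene`
#'   lists variants dropped for ambiguous gene assignment.
#' @export
select_lof_gene_sets <- function(gt, call_rate_min = 0.90,
                                 min_lof_per_gene = 2L) {
  v <- gt$variants
  st <- variant_stats(gt)
  multi <- if ("multi_gene" %in% names(v)) v$multi_gene else FALSE
  keep <- v$func_class %in% lof_classes() &
    !is.na(v$gene) & !multi &
    st$call_rate > call_rate_min
  excluded <- v$variant_id[v$func_class %in% lof_classes() & multi]
  sets <- v[keep, c("gene", "variant_id")]
  out <- dplyr::summarise(
    dplyr::group_by(sets, .data$gene),
    n_markers = dplyr::n(),
    variant_ids = list(.data$variant_id),
    .groups = "drop"
  )
  out <- out[out$n_markers >= min_lof_per_gene, ]
  out <- out[order(out$gene), ]
  attr(out, "excluded_multi_gene") <- excluded
  out
}
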