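# Shared fixtures, all built in code.

# A tiny handmade genotype table: 4 + 4 samples, 6 variants across 3
# genes ({1, 2, 5} would need more columns; this one is for basic
# plumbing).
toy_genotype_table <- function() {
  dosage <- rbind(
    c(0L, 1L, 0L, 2L, 0L, 1L),
    c(1L, 0L, 0L, 1L, 0L, 0L),
    c(0L, 0L, 1L, 1L, 0L, 1L),
    c(0L, 1L, 0L, 0L, 0L, 0L),
    c(2L, 1L, 1L, 0L, 1L, 1L),
    c(1L, 2L, 0L, 1L, 0L, 1L),
    c(1L, 1L, 1L, 0L, 1L, 0L),
    c(2L, 0L, 0L, 1L, 0L, 1L)
  )
  genotype_table(
    dosage,
    samples = tibble::tibble(
      sample_id = c(paste0("A", 1:4), paste0("B", 1:4)),
      cohort = rep(c("A", "B"), each = 4)
    ),
    variants = tibble::tibble(
      variant_id = sprintf("1:%d:A:G", 1:6 * 10),
      chrom = "1", pos = 1:6 * 10L, ref = "A", alt = "G",
      gene = c("g1", "g1", "g2", "g2", "g2", NA),
      func_class = c("stopgain", "stopgain", "stopgain",
                     "nonsynonymous SNV", "frameshift deletion",
                     "synonymous SNV")
    )
  )
}

# Frozen reference set of gene-level LOF cross-tabulations with their
# validated odds ratios, Woolf 95% intervals (3 decimals; NA encodes
# the zero-cell Null convention) and reported collapsed chi-squared
# p-values.  Used as a regression fixture for odds_ratio_woolf().
crosstab_reference <- function() {
  txt <- "
gene n_marker a1 a2 b1 b2 or lo hi p_chi
CD48 10 2 138 32 108 0.049 0.011 0.209 1.3e-06
ESPNL 4 18 38 44 12 0.129 0.055 0.302 2.04e-05
PRCP 8 34 78 69 43 0.272 0.156 0.473 6.47e-05
F2R 8 1 111 22 90 0.037 0.005 0.279 8.83e-05
TCTN1 9 2 124 23 103 0.072 0.017 0.314 0.000207
HPS1 13 19 163 49 133 0.316 0.178 0.563 0.000995
VPS72 3 12 30 30 12 0.16 0.062 0.412 0.001485
GPATCH3 2 16 12 28 0 NA NA NA 0.001598
RPAP3 4 6 50 24 32 0.16 0.059 0.434 0.002042
TTC27 7 2 96 18 80 0.093 0.021 0.411 0.002578
TBL2 4 5 51 22 34 0.152 0.052 0.439 0.002767
ALG12 8 28 84 55 57 0.345 0.196 0.608 0.002969
NIF3L1 4 4 52 20 36 0.138 0.044 0.439 0.003543
CLK1 2 3 25 16 12 0.09 0.022 0.369 0.003736
LY86 5 0 70 12 58 NA NA NA 0.004374
HSPA14 4 1 55 14 42 0.055 0.007 0.431 0.004617
SMYD5 2 9 19 22 6 0.129 0.039 0.43 0.006692
HCLS1 2 1 27 12 16 0.049 0.006 0.416 0.006978
MAK16 3 3 39 16 26 0.125 0.033 0.472 0.00933
TMEM242 3 9 33 24 18 0.205 0.079 0.533 0.010545
NDUFB4 4 0 56 9 47 NA NA NA 0.020472
TREM1 8 2 110 14 98 0.127 0.028 0.574 0.021371
ARG2 2 0 28 8 20 NA NA NA 0.025172
UMPS 3 3 39 14 28 0.154 0.04 0.586 0.030324
SLC35A5 3 3 39 14 28 0.154 0.04 0.586 0.030324
RPIA 3 0 42 8 34 NA NA NA 0.031466
VAMP5 2 4 24 14 14 0.167 0.046 0.607 0.042298
PRR5 4 2 54 12 44 0.136 0.029 0.639 0.042755
ATP2A2 2 0 28 7 21 NA NA NA 0.046012
TMEM19 2 0 28 7 21 NA NA NA 0.046012
"
  read.table(text = txt, header = TRUE, stringsAsFactors = FALSE)
}

# Write a small VCF + annotation + samples fixture to a temp dir.
write_toy_vcf_set <- function(dir = NULL, extra_vcf_lines = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("toyvcf")
    dir.create(dir)
  }
  vcf <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "##contig=<ID=1>",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3", "s4"), collapse = "\t"),
    "1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1\t./.",
    "1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t1/1\t1/1\t0/1\t1/1",
    extra_vcf_lines
  )
  writeLines(vcf, file.path(dir, "toy.vcf"))
  writeLines(c("variant_id\tgene\tfunc_class",
               "1:100:A:G\tg1\tstopgain",
               "1:200:C:T\tg1\tstopgain"),
             file.path(dir, "ann.tsv"))
  writeLines(c("sample_id\tcohort",
               "s1\tA", "s2\tA", "s3\tB", "s4\tB"),
             file.path(dir, "samples.tsv"))
  list(vcf = file.path(dir, "toy.vcf"),
       annotation = file.path(dir, "ann.tsv"),
       samples = file.path(dir, "samples.tsv"))
}

# The canonical 14 x 5 score-test toy: the first 5-marker gene of the
# generator under its default conditions with no differentiation and
# complete calls.
canonical_score_toy <- function() {
  cfg <- sim_config(seed = 1, fst = 0, missing_rate = 0)
  gt <- simulate_genotypes(cfg)
  sets <- select_lof_gene_sets(gt)
  g <- sets$gene[sets$n_markers == 5][1]
  idx <- match(sets$variant_ids[[match(g, sets$gene)]],
               gt$variants$variant_id)
  list(G = gt$dosage[, idx],
       y = as.integer(gt$samples$cohort == "B"))
}
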