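test_that("the exact Hardy-Weinberg test matches enumeration", {
  expect_equal(hwe_exact_test(5, 0, 0), 1)
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3)  # het in {0, 2} given 2 minor alleles
  p_hwe <- hwe_exact_test(25, 50, 25)
  expect_gte(p_hwe, 0.5)
  expect_equal(p_hwe, oracle_hwe(25, 50, 25), tolerance = 1e-12)
  expect_error(hwe_exact_test(0, 0, 0), "empty cohort")

  set.seed(31)
  for (i in 1:50) {
    n <- sample(2:40, 1)
    n_alt <- sample(0:(2 * n), 1)
    h_max <- min(n_alt, 2 * n - n_alt)
    hets <- seq(n_alt %% 2, h_max, by = 2)
    h <- sample(hets, 1)
    n2 <- (n_alt - h) / 2
    n0 <- n - h - n2
    expect_equal(hwe_exact_test(n0, h, n2), oracle_hwe(n0, h, n2),
                 tolerance = 1e-10)
  }
})

test_that("the QC cascade applies call-rate, MAF and HWE rules", {
  # 14 samples; call rate 13/14 kept, 12/14 removed
  n <- 14L
  mk <- function(x) matrix(x, nrow = n)
  dos <- cbind(
    c(rep(1L, 7), rep(0L, 6), NA),        # call rate 13/14 = 0.929
    c(rep(1L, 7), rep(0L, 5), NA, NA),    # call rate 12/14 = 0.857
    rep(0L, n),                            # MAF 0
    c(rep(0L, 7), rep(2L, 7))              # common, fully called: kept
  )
  gt <- genotype_table(
    dos,
    samples = tibble::tibble(sample_id = sprintf("s%02d", 1:n),
                             cohort = rep(c("A", "B"), each = 7)),
    variants = tibble::tibble(
      variant_id = paste0("v", 1:4), chrom = "1", pos = 1:4 * 10L,
      ref = "A", alt = "G", gene = NA_character_, func_class = "stopgain"
    )
  )
  res <- apply_variant_qc(gt)
  expect_identical(res$ledger$n_removed[res$ledger$filter == "call_rate"], 1L)
  kept <- res$genotypes$variants$variant_id
  expect_true("v1" %in% kept)
  expect_false("v2" %in% kept)
  expect_false("v3" %in% kept)  # MAF 0

  # ledger telescopes
  expect_identical(res$ledger$n_out[-nrow(res$ledger)],
                   res$ledger$n_in[-1])
  # idempotence
  res2 <- apply_variant_qc(res$genotypes)
  expect_identical(res2$genotypes$dosage, res$genotypes$dosage)
  expect_true(all(res2$ledger$n_removed == 0L))
  # no survivor violates the thresholds
  st <- variant_stats(res$genotypes)
  expect_true(all(st$call_rate > 0.90))
  expect_true(all(st$maf >= 0.01))
})

test_that("HWE removal requires failure in both cohorts by default", {
  # large cohorts so an extreme configuration can reach p < 5e-8
  n <- 200L
  fail_geno <- c(rep(0L, 100), rep(2L, 100))   # no hets: extreme HWE failure
  ok_geno <- c(rep(0L, 50), rep(1L, 100), rep(2L, 50))
  gt <- genotype_table(
    cbind(c(fail_geno, ok_geno),   # fails in A only -> kept
          c(fail_geno, fail_geno)  # fails in both -> removed
    ),
    samples = tibble::tibble(sample_id = sprintf("s%03d", 1:(2 * n)),
                             cohort = rep(c("A", "B"), each = n)),
    variants = tibble::tibble(
      variant_id = c("one_cohort", "both_cohorts"), chrom = "1",
      pos = c(10L, 20L), ref = "A", alt = "G",
      gene = NA_character_, func_class = "stopgain"
    )
  )
  expect_lt(hwe_exact_test(100, 0, 100), 5e-8)
  res <- apply_variant_qc(gt)
  expect_identical(res$genotypes$variants$variant_id, "one_cohort")
  res_either <- apply_variant_qc(gt, hwe_rule = "either")
  expect_identical(nrow(res_either$genotypes$variants), 0L)
})

test_that("gene sets keep only multi-variant LOF genes", {
  n <- 14L
  set.seed(2)
  m <- 8L
  dos <- matrix(rbinom(n * m, 2, 0.3), n, m)
  gt <- genotype_table(
    dos,
    samples = tibble::tibble(sample_id = sprintf("s%02d", 1:n),
                             cohort = rep(c("A", "B"), each = 7)),
    variants = tibble::tibble(
      variant_id = paste0("v", 1:m), chrom = "1", pos = 1:m * 10L,
      ref = "A", alt = "G",
      gene = c("g1", "g2", "g2", "g3", "g3", "g3", "g3", "g3"),
      func_class = c("stopgain", "stopgain", "frameshift insertion",
                     "stoploss", "nonsynonymous SNV", "stopgain",
                     "stopgain", "stopgain")
    )
  )
  sets <- select_lof_gene_sets(gt)
  expect_identical(sets$gene, c("g2", "g3"))
  expect_identical(sets$n_markers, c(2L, 5L))

  # synonymous variants are never selected
  gt$variants$func_class[2] <- "synonymous SNV"
  sets2 <- select_lof_gene_sets(gt)
  expect_false("g2" %in% sets2$gene)

  # ambiguous gene assignment excludes the variant, not the run
  gt$variants$multi_gene <- c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE,
                              FALSE, FALSE)
  sets3 <- select_lof_gene_sets(gt)
  expect_identical(sets3$n_markers[sets3$gene == "g3"], 4L)
  expect_identical(attr(sets3, "excluded_multi_gene"), "v4")
})

test_that("VCF reading orients dosage, drops multiallelics and logs them", {
  paths <- write_toy_vcf_set()
  gt <- read_study(paths$vcf, paths$annotation, paths$samples)
  # site 1: ALT is minor -> dosages as written
  expect_identical(unname(gt$dosage[, 1]), c(0L, 1L, 2L, NA))
  # site 2: ALT frequency 7/8 -> complemented so REF is counted
  expect_identical(unname(gt$dosage[, 2]), c(0L, 0L, 1L, 0L))
  expect_true(gt$variants$flipped[2])

  # triallelic record dropped and ledgered
  paths2 <- write_toy_vcf_set(
    extra_vcf_lines = "1\t300\t.\tA\tG,T\t.\tPASS\t.\tGT\t0/0\t0/1\t0/0\t0/0")
  gt2 <- read_study(paths2$vcf, paths2$annotation, paths2$samples)
  expect_identical(ncol(gt2$dosage), 2L)
  led <- gt2$ledger
  expect_identical(led$n_removed[led$filter == "multiallelic"], 1L)

  # unknown sample is named in the error
  dir <- withr::local_tempdir()
  paths3 <- write_toy_vcf_set(dir)
  writeLines(c("sample_id\tcohort", "s1\tA", "s2\tA", "s3\tB"),
             paths3$samples)
  expect_error(read_study(paths3$vcf, paths3$annotation, paths3$samples),
               "s4")
})
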