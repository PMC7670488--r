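mk_gt <- function(dosage, cohort = NULL) {
  n <- nrow(dosage); m <- ncol(dosage)
  if (is.null(cohort)) cohort <- rep(c("A", "B"), length.out = n)
  genotype_table(
    dosage,
    samples = tibble::tibble(sample_id = sprintf("s%02d", seq_len(n)),
                             cohort = cohort),
    variants = tibble::tibble(variant_id = paste0("v", seq_len(m)),
                              chrom = "1", pos = seq_len(m) * 10L,
                              ref = "A", alt = "G", gene = NA_character_,
                              func_class = "synonymous SNV")
  )
}

test_that("IBS distances follow the allele-sharing definition", {
  gt <- mk_gt(rbind(c(0L, 1L), c(0L, 1L), c(2L, 0L), c(1L, 2L),
                    c(0L, 2L), c(2L, 0L)))
  d <- ibs_distance(gt)
  expect_equal(unname(d[1, 2]), 0)      # identical vectors
  expect_equal(unname(d[5, 6]), 1)      # (0,2) vs (2,0): zero sharing
  expect_equal(unname(d[1, 3]), 0.75)   # |0-2|/2 = 1, |1-0|/2 = 0.5
  expect_equal(unname(d[2, 4]), 0.5)    # (0,1) vs (1,2): 0.5, 0.5
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
})

test_that("IBS distance is metric-like on simulated data", {
  gt <- simulate_genotypes(sim_config(seed = 41, n_genes_variant = 50,
                                      n_neutral_variants = 200))
  d <- ibs_distance(gt)
  expect_true(isSymmetric(d))
  expect_true(all(d >= 0 & d <= 1))
  n <- nrow(d)
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
  }
  # a pair with no shared calls is an error naming the pair
  gt2 <- mk_gt(rbind(c(0L, NA), c(NA, 1L), c(1L, 1L), c(0L, 0L)))
  expect_error(ibs_distance(gt2), "s01 and s02")
})

test_that("genotype PCA separates differentiated cohorts and is stabilised", {
  ok <- vapply(1:10, function(s) {
    gt <- simulate_genotypes(sim_config(seed = 700 + s, fst = 0.3,
                                        n_genes_variant = 0,
                                        n_neutral_variants = 1000,
                                        missing_rate = 0))
    pca <- pca_genotypes(gt, k = 2)
    a <- pca$scores$PC1[pca$scores$cohort == "A"]
    b <- pca$scores$PC1[pca$scores$cohort == "B"]
    max(a) < min(b) || max(b) < min(a)   # no overlap on PC1
  }, logical(1))
  expect_gte(mean(ok), 0.9)

  gt <- simulate_genotypes(sim_config(seed = 43, missing_rate = 0))
  pca <- pca_genotypes(gt, k = 3)
  expect_gte(pca$scores$PC1[1], 0)  # sign stabilised per component
  expect_gte(pca$scores$PC2[1], 0)

  # eigenvalue sum equals the total variance of the normalised matrix
  st <- variant_stats(gt)
  x <- gt$dosage[, st$maf > 0 & st$maf < 1, drop = FALSE]
  tot <- colSums(x); nc <- colSums(!is.na(x))
  p_hat <- (1 + tot) / (2 + 2 * nc)
  xs <- sweep(sweep(x, 2, tot / nc, "-"), 2, sqrt(2 * p_hat * (1 - p_hat)), "/")
  expect_equal(sum(pca$eigenvalues), sum(xs^2) / (nrow(x) - 1),
               tolerance = 1e-8)

  mono <- mk_gt(matrix(1L, 4, 3))
  expect_error(pca_genotypes(mono), "no polymorphic")
  expect_warning(pca_genotypes(gt, k = 50), "clamped")
})

test_that("PCA outlier flagging finds a displaced sample and only it", {
  spread <- seq(-1, 1, length.out = 7)
  scores <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:14),
    cohort = rep(c("A", "B"), each = 7),
    PC1 = c(spread, spread),
    PC2 = c(rev(spread), spread)
  )
  scores$PC1[3] <- mean(scores$PC1[c(1:2, 4:7)]) +
    10 * sd(scores$PC1[c(1:2, 4:7)])
  pca <- structure(list(scores = scores, eigenvalues = c(2, 1)),
                   class = "pca_genotypes")
  expect_identical(detect_outliers_pca(pca, n_sd = 3), "s03")
  expect_identical(length(detect_outliers_pca(pca, n_sd = 0)), 14L)

  # homogeneous cohorts: leave-one-out z at n = 7 has t-like tails, so
  # occasional spurious flags are expected; the rate must stay small
  frac <- vapply(1:40, function(s) {
    set.seed(1200 + s)
    sc <- tibble::tibble(sample_id = sprintf("s%02d", 1:14),
                         cohort = rep(c("A", "B"), each = 7),
                         PC1 = rnorm(14), PC2 = rnorm(14))
    p <- structure(list(scores = sc, eigenvalues = c(2, 1)),
                   class = "pca_genotypes")
    length(detect_outliers_pca(p, n_sd = 3)) / 14
  }, numeric(1))
  expect_lte(mean(frac), 0.15)
})

test_that("neighbour joining recovers additive trees exactly", {
  # 2 taxa: symmetric split
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  t2 <- neighbor_joining(d2)
  expect_setequal(t2$tip.label, c("a", "b"))
  expect_equal(sort(t2$edge.length), c(0.2, 0.2))

  # 3 taxa: closed-form star branches
  d3 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  d3["a", "b"] <- d3["b", "a"] <- 0.6
  d3["a", "c"] <- d3["c", "a"] <- 0.8
  d3["b", "c"] <- d3["c", "b"] <- 0.4
  t3 <- neighbor_joining(d3)
  cp <- ape::cophenetic.phylo(t3)
  expect_equal(cp[rownames(d3), colnames(d3)], d3, tolerance = 1e-12)
  b_a <- (0.6 + 0.8 - 0.4) / 2
  expect_equal(max(t3$edge.length), b_a)

  # random additive trees up to 12 leaves: exact topology and lengths
  for (s in 1:15) {
    set.seed(800 + s)
    n <- sample(4:12, 1)
    tr <- ape::rtree(n)
    d <- ape::cophenetic.phylo(tr)
    got <- neighbor_joining(d)
    expect_equal(ape::dist.topo(ape::unroot(tr), got), 0,
                 ignore_attr = TRUE)
    expect_lt(max(abs(ape::cophenetic.phylo(got)[rownames(d), colnames(d)] -
                        d)), 1e-9)
  }

  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(neighbor_joining(bad), "symmetric")
})

test_that("Newick output round-trips through ape", {
  tr <- neighbor_joining(ibs_distance(
    simulate_genotypes(sim_config(seed = 47, n_genes_variant = 20,
                                  n_neutral_variants = 100))))
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, path)
  back <- ape::read.tree(path)
  expect_setequal(back$tip.label, tr$tip.label)
  expect_equal(ape::dist.topo(back, tr), 0, ignore_attr = TRUE)
})

test_that("observed heterozygosity matches its definition and HWE", {
  gt_all_het <- mk_gt(matrix(1L, 6, 10))
  expect_true(all(observed_heterozygosity(gt_all_het)$heterozygosity == 1))
  gt_no_het <- mk_gt(matrix(rep(c(0L, 2L), 30), 6, 10))
  expect_true(all(observed_heterozygosity(gt_no_het)$heterozygosity == 0))

  set.seed(53)
  gt_hwe <- mk_gt(matrix(rbinom(40 * 2000, 2, 0.3), 40, 2000))
  het <- observed_heterozygosity(gt_hwe)
  expect_equal(het$heterozygosity, rep(2 * 0.3 * 0.7, 2), tolerance = 0.02)
})
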