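mk_expr <- function(counts, lengths = rep(1000, nrow(counts)),
                    cohort = rep(c("A", "B"), each = ncol(counts) / 2)) {
  expression_table(
    counts,
    genes = tibble::tibble(gene_id = sprintf("g%03d", seq_len(nrow(counts))),
                           length = lengths),
    samples = tibble::tibble(sample_id = sprintf("s%02d", seq_len(ncol(counts))),
                             cohort = cohort),
    unit = "counts"
  )
}

test_that("TPM conversion normalises per-kilobase rates to a million", {
  tpm <- tpm_from_counts(matrix(c(10, 10), 2, 1), c(1000, 2000))
  expect_equal(as.vector(tpm), c(2 / 3, 1 / 3) * 1e6, tolerance = 1e-9)
  expect_equal(as.vector(tpm_from_counts(matrix(5, 1, 1), 500)), 1e6)

  set.seed(61)
  counts <- matrix(rpois(200, 50), 20, 10)
  lens <- runif(20, 300, 3000)
  tpm1 <- tpm_from_counts(counts, lens)
  expect_true(all(abs(colSums(tpm1) - 1e6) < 1e-3))
  # scale invariance within a sample
  tpm2 <- tpm_from_counts(counts * 2, lens)
  expect_equal(tpm1, tpm2, tolerance = 1e-12)

  counts0 <- counts; counts0[, 3] <- 0
  colnames(counts0) <- paste0("s", 1:10)
  expect_error(tpm_from_counts(counts0, lens), "s3")
})

test_that("per-gene models pool variances over the two cohorts", {
  # log2(count + 1) responses: A = (1, 1), B = (3, 3)
  et <- mk_expr(matrix(c(1, 1, 7, 7), 1, 4), lengths = 1000)
  f <- fit_gene_models(et, response = "log2_count")
  expect_equal(f$lfc, 2)
  expect_equal(f$s2, 0)
  # A = (0, 2), B = (1, 3) on the log scale
  et2 <- mk_expr(matrix(c(0, 3, 1, 7), 1, 4), lengths = 1000)
  f2 <- fit_gene_models(et2, response = "log2_count")
  expect_equal(f2$lfc, 1)
  expect_equal(f2$s2, 2)
  expect_equal(f2$df, 2)
  # identical groups: no fold change
  et3 <- mk_expr(matrix(c(4, 9, 4, 9), 1, 4), lengths = 1000)
  expect_equal(fit_gene_models(et3, response = "log2_count")$lfc, 0)

  # all-zero genes are dropped and recorded
  cm <- matrix(rpois(40, 20), 10, 4)
  cm[4, ] <- 0
  f4 <- fit_gene_models(mk_expr(cm), response = "log2_count")
  expect_identical(nrow(f4), 9L)
  expect_identical(attr(f4, "dropped_genes"), "g004")
})

test_that("empirical-Bayes moderation recovers its prior and shrinks", {
  # equal variances collapse to the common value
  eb0 <- ebayes_moderate(rep(2.5, 50), 10)
  expect_identical(eb0$d0, Inf)
  expect_equal(eb0$s0_sq, 2.5, tolerance = 1e-9)
  expect_equal(eb0$s2_post, rep(2.5, 50), tolerance = 1e-9)

  # hierarchical parameter recovery, checked against limma's estimator
  set.seed(63)
  d0 <- 8; s0 <- 4; dg <- 12; n_genes <- 5000
  sigma2 <- s0 * d0 / rchisq(n_genes, d0)
  s2 <- sigma2 * rchisq(n_genes, dg) / dg
  eb <- ebayes_moderate(s2, dg)
  expect_gte(eb$d0, 6); expect_lte(eb$d0, 10)
  expect_gte(eb$s0_sq, 3.6); expect_lte(eb$s0_sq, 4.4)
  fd <- limma::fitFDist(s2, dg)
  expect_equal(eb$d0, fd$df2, tolerance = 1e-6)
  expect_equal(eb$s0_sq, fd$scale, tolerance = 1e-6)

  # moderated values are convex combinations
  expect_true(all(eb$s2_post >= pmin(s2, eb$s0_sq) - 1e-12))
  expect_true(all(eb$s2_post <= pmax(s2, eb$s0_sq) + 1e-12))
  # an outlying variance is pulled strictly inward
  set.seed(64)
  s2_out <- c(rchisq(200, 10) / 10, 50)
  ebo <- ebayes_moderate(s2_out, 10)
  expect_lt(ebo$d0, Inf)
  expect_lt(ebo$s2_post[201], 50)
  expect_gt(ebo$s2_post[201], ebo$s0_sq)

  expect_error(ebayes_moderate(rep(0, 20), 10), "degenerate")
})

test_that("moderated t statistics hit their distributional limits", {
  fits <- tibble::tibble(gene = c("a", "b"), mean_expr = 1,
                         lfc = c(0, 1), s2 = c(1, 1), df = 10)
  attr(fits, "n_a") <- 4; attr(fits, "n_b") <- 4
  prior <- structure(list(d0 = Inf, s0_sq = 1, s2_post = c(1, 1)),
                     class = "ebayes_prior")
  res <- moderated_t_tests(fits, prior)
  expect_equal(res$p[1], 1)
  z <- 1 / sqrt(1 / 4 + 1 / 4)
  expect_equal(res$p[2], 2 * pnorm(z, lower.tail = FALSE), tolerance = 1e-12)

  # finite prior reduces to a t on d0 + dg df
  prior2 <- structure(list(d0 = 4, s0_sq = 1, s2_post = c(1, 1)),
                      class = "ebayes_prior")
  res2 <- moderated_t_tests(fits, prior2)
  expect_equal(res2$p[2], 2 * pt(z, df = 14, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("the adaptive fold-change threshold is mean + 2 SD of |lfc|", {
  expect_equal(adaptive_lfc_threshold(c(1, 1, 1)), 1)
  expect_equal(adaptive_lfc_threshold(c(0, 0, 0, 4)), 5)
  expect_equal(adaptive_lfc_threshold(c(-2, 2)), 2)
  expect_error(adaptive_lfc_threshold(1), "at least 2")
})

test_that("BH adjustment is a monotone step-up capped at 1", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.04, 6)), rep(0.04, 6))
  set.seed(65)
  p <- runif(100)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  o <- order(p)
  expect_true(all(diff(adj[o]) >= -1e-12))
  # step-up recomputation oracle
  m <- length(p)
  expected <- rev(cummin(rev(sort(p) * m / seq_len(m))))[rank(p, ties.method = "first")]
  expect_equal(adj, pmin(expected, 1), tolerance = 1e-12)
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
})

test_that("DEG calling controls errors on null data and respects alpha", {
  et <- simulate_expression(sim_config(seed = 67, n_genes_expr = 2000,
                                       n_de_genes = 0))
  de <- run_de(et)
  expect_lte(sum(de$significant), 0.05 * nrow(de))
  de0 <- call_degs(tidy(de), alpha = 0)
  expect_identical(sum(de0$significant), 0L)

  g <- glance(de)
  expect_equal(g$n_up + g$n_down, sum(de$significant))
  expect_true(all(de$p_adj >= de$p))
})

test_that("hypergeometric overrepresentation matches enumeration", {
  # universe of 20, one set of 5, 5 hits, overlap 3
  universe <- sprintf("u%02d", 1:20)
  sets <- list(S = universe[1:5], none = character())
  hits <- universe[c(1, 2, 3, 10, 11)]
  res <- ora_hypergeometric(hits, universe, sets)
  p_expected <- sum(vapply(3:5, function(k) {
    choose(5, k) * choose(15, 5 - k) / choose(20, 5)
  }, numeric(1)))
  expect_equal(res$p[res$set == "S"], p_expected, tolerance = 1e-12)

  # a fully-hit set attains the minimum possible p
  res2 <- ora_hypergeometric(universe[1:5], universe,
                             list(S = universe[1:5],
                                  T = universe[6:10]))
  expect_lt(res2$p[res2$set == "S"], res2$p[res2$set == "T"])
  expect_equal(res2$p[res2$set == "S"],
               1 / choose(20, 5), tolerance = 1e-12)
  # zero overlap sits in the upper tail
  expect_gte(res2$p[res2$set == "T"], 0.5)

  expect_error(ora_hypergeometric("x", character(), sets), "universe")
  expect_error(ora_hypergeometric("zz", universe, sets), "subset")
})

test_that("GMT files parse into named member lists", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg2\tg4"), path)
  gs <- read_gmt(path)
  expect_identical(names(gs), c("setA", "setB"))
  expect_identical(gs$setB, c("g2", "g4"))
  writeLines("bad\tonly_two_fields", path)
  expect_error(read_gmt(path), "fewer than 3")
})
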