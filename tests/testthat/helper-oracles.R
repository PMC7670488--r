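# Independent brute-force oracles used across the suite.  These are
# deliberately naive re-derivations, kept separate from the package's
# own code paths.

# Exact Hardy-Weinberg test by direct enumeration of genotype
# configurations (multinomial coefficients, no shared code with
# hwe_exact_test's recursion over heterozygote counts).
oracle_hwe <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  n_alt <- 2 * n2 + n1
  hets <- 0:min(2 * n - n_alt, n_alt)
  hets <- hets[(n_alt - hets) %% 2 == 0 & (n_alt - hets) >= 0 &
                 (2 * n - n_alt - hets) >= 0]
  logp <- vapply(hets, function(h) {
    aa <- (n_alt - h) / 2
    rr <- n - h - aa
    lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(rr) +
      h * log(2)  # normalising constant cancels below
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n1, hets)]
  sum(p[p <= obs * (1 + 1e-12)])
}

# Two-sided Fisher p by explicit enumeration of all tables with the
# observed margins.
oracle_fisher <- function(a, b, c, d) {
  m1 <- a + b; k <- a + c; m2 <- c + d
  support <- max(0, k - m2):min(k, m1)
  logp <- vapply(support, function(x) {
    lchoose(m1, x) + lchoose(m2, k - x) - lchoose(m1 + m2, k)
  }, numeric(1))
  p <- exp(logp)
  sum(p[p <= p[match(a, support)] * (1 + 1e-7)])
}

# Hudson FST estimator: mean of per-variant numerators over mean of
# denominators, computed directly from cohort allele frequencies.
oracle_hudson_fst <- function(gt) {
  is_a <- gt$samples$cohort == "A"
  p1 <- colMeans(gt$dosage[is_a, , drop = FALSE], na.rm = TRUE) / 2
  p2 <- colMeans(gt$dosage[!is_a, , drop = FALSE], na.rm = TRUE) / 2
  # n1/n2 are sampled allele counts (2 per called diploid)
  n1 <- 2 * colSums(!is.na(gt$dosage[is_a, , drop = FALSE]))
  n2 <- 2 * colSums(!is.na(gt$dosage[!is_a, , drop = FALSE]))
  ok <- n1 > 2 & n2 > 2 & !is.na(p1) & !is.na(p2)
  p1 <- p1[ok]; p2 <- p2[ok]; n1 <- n1[ok]; n2 <- n2[ok]
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  mean(num) / mean(den)
}

# Textbook Pearson chi-squared via observed/expected cell sums.
oracle_chi2_oe <- function(a1, a2, b1, b2) {
  o <- matrix(c(a1, a2, b1, b2), 2, 2, byrow = TRUE)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  sum((o - e)^2 / e)
}

# Tail of a chi-squared mixture by plain Monte Carlo.
oracle_quadform_mc <- function(q, lambda, n_draws = 1e6, seed = 1) {
  set.seed(seed)
  draws <- colSums(lambda * matrix(rchisq(length(lambda) * n_draws, df = 1),
                                   nrow = length(lambda)))
  mean(draws >= q)
}
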