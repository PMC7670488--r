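#' Per-gene two-group linear models on the log scale
#'
#' Fits the two-group mean model to `log2(value + 1)` per gene: the
#' log2 fold change is `mean(B) - mean(A)` and the residual variance is
#' the pooled within-group variance on `n_A + n_B - 2` degrees of
#' freedom.  The response is log2(TPM + 1) by default; `response =
#' "log2_count"` models log2(count + 1) instead.  Genes with zero counts
#' in every sample are dropped before fitting (recorded in the
#' `dropped_genes` attribute).
#'
#' @param expr an [expression_table()].
#' @param response `"log2_tpm"` (default) or `"log2_count"`.
#' @return tibble with columns `gene`, `mean_expr`, `lfc`, `s2`, `df`,
#'   and attributes `n_a`, `n_b`, `dropped_genes`.
#' @export
fit_gene_models <- function(expr, response = c("log2_tpm", "log2_count")) {
  response <- arg_match(response)
  stopifnot(inherits(expr, "expression_table"))
  is_a <- expr$samples$cohort == "A"
  n_a <- sum(is_a); n_b <- sum(!is_a)
  if (n_a < 2 || n_b < 2) abort("need at least 2 samples per cohort")
  vals <- if (response == "log2_tpm") as_tpm(expr)$values else expr$values
  keep <- rowSums(expr$values) > 0
  y <- log2(vals[keep, , drop = FALSE] + 1)
  ya <- y[, is_a, drop = FALSE]
  yb <- y[, !is_a, drop = FALSE]
  ma <- rowMeans(ya); mb <- rowMeans(yb)
  ss <- rowSums((ya - ma)^2) + rowSums((yb - mb)^2)
  df <- n_a + n_b - 2
  fits <- tibble(gene = expr$genes$gene_id[keep],
                 mean_expr = unname(rowMeans(y)),
                 lfc = unname(mb - ma), s2 = unname(ss / df), df = df)
  attr(fits, "n_a") <- n_a
  attr(fits, "n_b") <- n_b
  attr(fits, "dropped_genes") <- expr$genes$gene_id[!keep]
  fits
}

# Inverse of the trigamma function by Newton iteration on 1/psi'.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (iter in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Empirical-Bayes moderation of per-gene variances
#'
#' Estimates the scaled inverse chi-squared prior (`d0` degrees of
#' freedom, `s0_sq` scale) for the per-gene residual variances by the
#' log-variance moment method: with
#' `e_g = log(s_g^2) - digamma(df_g / 2) + log(df_g / 2)`,
#' `d0` solves `trigamma(d0 / 2) = var(e) - mean(trigamma(df_g / 2))`
#' (`d0 = Inf` when the right-hand side is non-positive) and
#' `s0_sq = exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))`.  The
#' moderated variance is the shrunk combination
#' `(d0 * s0_sq + df * s2) / (d0 + df)`.  Genes with zero variance
#' contribute nothing to the moment estimation but are shrunk like any
#' other gene.
#'
#' @param s2 per-gene residual variances.
#' @param df per-gene residual degrees of freedom (scalar or vector).
#' @return list of class `ebayes_prior`: `d0`, `s0_sq`, `s2_post`.
#' @export
ebayes_moderate <- function(s2, df) {
  if (length(df) == 1) df <- rep(df, length(s2))
  stopifnot(length(s2) == length(df))
  if (all(s2 <= 0)) abort("degenerate expression matrix: all variances zero")
  ok <- s2 > 0 & is.finite(s2)
  if (sum(ok) < 10) abort("need at least 10 genes with positive variance")
  e <- log(s2[ok]) - digamma(df[ok] / 2) + log(df[ok] / 2)
  rhs <- var(e) - mean(trigamma(df[ok] / 2))
  if (is.finite(rhs) && rhs > 0) {
    d0 <- 2 * trigamma_inverse(rhs)
    s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    s2_post <- (d0 * s0_sq + df * s2) / (d0 + df)
  } else {
    # no excess spread beyond sampling noise: complete shrinkage to the
    # common (geometric-mean) variance
    d0 <- Inf
    s0_sq <- exp(mean(log(s2[ok])))
    s2_post <- rep(s0_sq, length(s2))
  }
  structure(list(d0 = d0, s0_sq = s0_sq, s2_post = s2_post),
            class = "ebayes_prior")
}

#' Moderated t-tests
#'
#' `t_g = lfc_g / (s_post_g * sqrt(1/n_A + 1/n_B))` with two-sided
#' p-values from the t distribution on `d0 + df` degrees of freedom
#' (standard normal when `d0 = Inf`).
#'
#' @param fits tibble from [fit_gene_models()].
#' @param prior an [ebayes_moderate()] result for the same genes.
#' @return `fits` with added columns `s2_post`, `t_mod`, `p`.
#' @export
moderated_t_tests <- function(fits, prior) {
  n_a <- attr(fits, "n_a"); n_b <- attr(fits, "n_b")
  stopifnot(!is.null(n_a), !is.null(n_b),
            length(prior$s2_post) == nrow(fits))
  se <- sqrt(prior$s2_post * (1 / n_a + 1 / n_b))
  t_mod <- ifelse(se > 0, fits$lfc / se, ifelse(fits$lfc == 0, 0, Inf * sign(fits$lfc)))
  df_tot <- prior$d0 + fits$df
  p <- if (is.infinite(prior$d0)) {
    2 * stats::pnorm(abs(t_mod), lower.tail = FALSE)
  } else {
    2 * pt(abs(t_mod), df = df_tot, lower.tail = FALSE)
  }
  out <- fits
  out$s2_post <- prior$s2_post
  out$t_mod <- t_mod
  out$p <- p
  attr(out, "n_a") <- n_a; attr(out, "n_b") <- n_b
  out
}

#' Adaptive absolute log2-fold-change threshold
#'
#' `T = mean(|lfc|) + 2 * sd(|lfc|)` with the sample (n - 1) standard
#' deviation, computed over the full fitted fold-change vector.
#'
#' @param lfcs log2 fold changes.
#' @return the threshold.
#' @export
adaptive_lfc_threshold <- function(lfcs) {
  if (length(lfcs) < 2) abort("need at least 2 genes")
  a <- abs(lfcs)
  mean(a) + 2 * sd(a)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, returned in input order.
#'
#' @param pvals p-values in (0, 1].
#' @return adjusted p-values.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals <= 0 | pvals > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

#' Call differentially expressed genes
#'
#' A gene is significant when its raw p-value is below `alpha` and its
#' absolute log2 fold change exceeds the adaptive threshold
#' [adaptive_lfc_threshold()] computed on the full fold-change vector;
#' `significant_fdr` applies the same fold-change rule with the
#' BH-adjusted p-value.  Direction is the sign of the fold change (B
#' relative to A).
#'
#' @param results tibble from [moderated_t_tests()] (columns `lfc`,
#'   `p`).
#' @param alpha raw p-value cutoff.
#' @return object of class `de_result`: the input tibble with `p_adj`,
#'   `significant`, `significant_fdr`, `direction`, plus attributes
#'   `lfc_threshold`, `n_up`, `n_down`, `n_up_fdr`, `n_down_fdr`.
#' @export
call_degs <- function(results, alpha = 0.05) {
  thr <- adaptive_lfc_threshold(results$lfc)
  out <- results
  out$p_adj <- bh_adjust(out$p)
  out$significant <- out$p < alpha & abs(out$lfc) > thr
  out$significant_fdr <- out$p_adj < alpha & abs(out$lfc) > thr
  out$direction <- ifelse(out$lfc > 0, "up", ifelse(out$lfc < 0, "down", "none"))
  attr(out, "lfc_threshold") <- thr
  attr(out, "alpha") <- alpha
  attr(out, "n_up") <- sum(out$significant & out$direction == "up")
  attr(out, "n_down") <- sum(out$significant & out$direction == "down")
  attr(out, "n_up_fdr") <- sum(out$significant_fdr & out$direction == "up")
  attr(out, "n_down_fdr") <- sum(out$significant_fdr & out$direction == "down")
  class(out) <- c("de_result", class(out))
  out
}

#' Differential expression, end to end
#'
#' Composes [fit_gene_models()], [ebayes_moderate()],
#' [moderated_t_tests()] and [call_degs()].
#'
#' @inheritParams fit_gene_models
#' @inheritParams call_degs
#' @return a `de_result` tibble whose `prior` attribute holds the
#'   fitted [ebayes_moderate()] prior.
#' @export
run_de <- function(expr, alpha = 0.05, response = c("log2_tpm", "log2_count")) {
  fits <- fit_gene_models(expr, response = response)
  prior <- ebayes_moderate(fits$s2, fits$df)
  res <- call_degs(moderated_t_tests(fits, prior), alpha = alpha)
  attr(res, "prior") <- prior
  res
}

#' Hypergeometric gene-set overrepresentation
#'
#' Per gene set, the upper-tail hypergeometric probability of observing
#' at least the overlap between the hit list and the set, both
#' intersected with the universe; BH adjustment across sets.
#'
#' @param hit_genes character vector of significant genes (must be a
#'   subset of `universe`).
#' @param universe character vector of all tested genes.
#' @param gene_sets named list of character vectors (see [read_gmt()]).
#' @return tibble with columns `set`, `set_size`, `n_hits`, `overlap`,
#'   `p`, `p_adj`.
#' @export
ora_hypergeometric <- function(hit_genes, universe, gene_sets) {
  universe <- unique(universe)
  if (length(universe) == 0) abort("empty universe")
  hit_genes <- unique(hit_genes)
  if (!all(hit_genes %in% universe)) abort("hit genes must be a subset of the universe")
  n_u <- length(universe)
  n_h <- length(hit_genes)
  rows <- purrr::imap(gene_sets, function(members, name) {
    set_u <- intersect(members, universe)
    k <- length(intersect(set_u, hit_genes))
    p <- phyper(k - 1, length(set_u), n_u - length(set_u), n_h,
                lower.tail = FALSE)
    tibble(set = name, set_size = length(set_u), n_hits = n_h,
           overlap = k, p = p)
  })
  out <- bind_rows(rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  arrange(out, .data$p)
}
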