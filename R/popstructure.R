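#' Identity-by-state distance matrix
#'
#' For each sample pair, over the variants called in both, the
#' per-variant allele-sharing score is `1 - |g_i - g_j| / 2`; the pair's
#' IBS is the mean score and the distance is `1 - IBS`, giving a
#' symmetric matrix in `[0, 1]` with zero diagonal.
#'
#' @param gt a [genotype_table()].
#' @return symmetric numeric matrix with sample ids as dimnames.
#' @export
ibs_distance <- function(gt) {
  d <- gt$dosage
  n <- nrow(d)
  if (n < 2) abort("need at least 2 samples")
  out <- matrix(0, n, n, dimnames = list(rownames(d), rownames(d)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(d[i, ]) & !is.na(d[j, ])
      if (!any(ok)) {
        abort(paste0("samples ", rownames(d)[i], " and ", rownames(d)[j],
                     " share no called variants"))
      }
      dist_ij <- mean(abs(d[i, ok] - d[j, ok]) / 2)
      out[i, j] <- out[j, i] <- dist_ij
    }
  }
  out
}

#' Genotype principal component analysis
#'
#' Columns are normalised in the smartPCA convention: the allele
#' frequency is the posterior estimate `(1 + sum g) / (2 + 2 n_called)`
#' (plain MLE via `freq = "mle"`), each column is centred on its
#' observed mean and scaled by `sqrt(2 p (1 - p))`, missing entries are
#' set to 0 after centring, and monomorphic columns are dropped.
#' Coordinates come from the singular value decomposition over samples;
#' each component is sign-stabilised so the first sample's coordinate is
#' non-negative.
#'
#' @param gt a [genotype_table()].
#' @param k number of components to return (clamped to `n_samples - 1`
#'   with a warning).
#' @param freq `"posterior"` (add-one, default) or `"mle"` allele
#'   frequency in the scaling.
#' @return object of class `pca_genotypes`: `scores` tibble
#'   (`sample_id`, `cohort`, `PC1` ... `PCk`), `eigenvalues` (all
#'   components, descending), `n_variants_used`.
#' @export
pca_genotypes <- function(gt, k = 2, freq = c("posterior", "mle")) {
  freq <- arg_match(freq)
  n <- n_samples(gt)
  if (n < 2) abort("need at least 2 samples")
  if (k > n - 1) {
    warn(sprintf("k = %d clamped to n_samples - 1 = %d", k, n - 1))
    k <- n - 1
  }
  d <- gt$dosage
  n_called <- colSums(!is.na(d))
  tot <- colSums(d, na.rm = TRUE)
  mono <- vapply(seq_len(ncol(d)), function(j) {
    v <- d[!is.na(d[, j]), j]
    length(v) == 0 || all(v == v[1])
  }, logical(1))
  if (all(mono)) abort("no polymorphic variants")
  d <- d[, !mono, drop = FALSE]
  n_called <- n_called[!mono]
  tot <- tot[!mono]
  p_hat <- if (freq == "posterior") {
    (1 + tot) / (2 + 2 * n_called)
  } else {
    tot / (2 * n_called)
  }
  mu <- tot / n_called
  x <- sweep(d, 2, mu, "-")
  x <- sweep(x, 2, sqrt(2 * p_hat * (1 - p_hat)), "/")
  x[is.na(x)] <- 0
  sv <- svd(x)
  eig <- sv$d^2 / (n - 1)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], nrow = k)
  flip <- scores[1, ] < 0
  scores[, flip] <- -scores[, flip, drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(
    list(scores = dplyr::bind_cols(gt$samples, as_tibble(scores)),
         eigenvalues = eig, n_variants_used = ncol(d)),
    class = "pca_genotypes"
  )
}

#' @export
print.pca_genotypes <- function(x, ...) {
  pve <- 100 * x$eigenvalues[1:2] / sum(x$eigenvalues)
  cat(sprintf("<pca_genotypes> %d variants; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              x$n_variants_used, pve[1], pve[2]))
  invisible(x)
}

#' Flag PCA outlier samples
#'
#' Flags samples whose PC1 or PC2 coordinate deviates from its cohort
#' centre by at least `n_sd` cohort standard deviations, where centre
#' and spread are computed leaving the tested sample out.  (With the
#' sample included, the deviation/SD ratio is algebraically capped at
#' `(n-1)/sqrt(n)` — about 2.27 for a cohort of 7 — so a 3-SD rule
#' could never fire in the designs this package targets.)  Flagging
#' only: removing a flagged sample is an explicit pipeline decision.
#'
#' @param pca a [pca_genotypes()] result with at least 2 components.
#' @param n_sd deviation multiplier.
#' @return character vector of flagged sample ids.
#' @export
detect_outliers_pca <- function(pca, n_sd = 3) {
  sc <- pca$scores
  if (nrow(sc) < 3) abort("need at least 3 samples")
  pcs <- intersect(c("PC1", "PC2"), names(sc))
  flagged <- logical(nrow(sc))
  for (coh in unique(sc$cohort)) {
    idx <- which(sc$cohort == coh)
    for (pc in pcs) {
      v <- sc[[pc]][idx]
      for (i in seq_along(v)) {
        rest <- v[-i]
        if (length(rest) < 2) next
        s <- stats::sd(rest)
        if (!is.finite(s)) s <- 0
        if (abs(v[i] - mean(rest)) >= n_sd * s) flagged[idx[i]] <- TRUE
      }
    }
  }
  sc$sample_id[flagged]
}

#' Neighbour-joining tree from a distance matrix
#'
#' The Saitou-Nei agglomeration with the Studier-Keppler criterion
#' `Q(i, j) = (r - 2) d(i, j) - R_i - R_j`: the minimising pair is
#' joined (ties broken by the lexicographically smallest pair of cluster
#' labels), branch lengths follow the standard split formula with
#' negative branches clamped to zero and the deficit moved to the sister
#' branch, and the final three clusters meet at an unrooted
#' trifurcation.  On an additive distance matrix the generating tree is
#' recovered exactly.
#'
#' @param d symmetric non-negative distance matrix with zero diagonal
#'   and labelled rows, e.g. from [ibs_distance()].
#' @return an [ape::as.phylo] `phylo` object (unrooted, with branch
#'   lengths).
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2) abort("need at least 2 taxa")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(n))
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-12)) ||
      any(d < 0) || any(abs(diag(d)) > 1e-12)) {
    abort("distance matrix must be symmetric, non-negative, zero-diagonal")
  }
  tips <- rownames(d)
  if (n == 2) {
    tree <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
                 edge.length = rep(d[1, 2] / 2, 2),
                 tip.label = tips, Nnode = 1L)
    class(tree) <- "phylo"
    return(tree)
  }

  # Each active cluster carries its Newick substring and a label (its
  # lexicographically smallest tip) used only for tie-breaking.
  newick <- tips
  label <- tips
  dd <- d
  fmt <- function(x) sprintf("%.12g", max(x, 0))

  while (length(newick) > 3L) {
    r <- length(newick)
    rs <- rowSums(dd)
    q <- (r - 2) * dd - outer(rs, rs, "+")
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    lab_pair <- vapply(seq_len(nrow(cand)), function(ii) {
      paste(sort(c(label[cand[ii, 1]], label[cand[ii, 2]])), collapse = "\r")
    }, character(1))
    pick <- cand[order(lab_pair)[1], ]
    i <- pick[[1]]; j <- pick[[2]]
    bi <- 0.5 * dd[i, j] + (rs[i] - rs[j]) / (2 * (r - 2))
    bj <- dd[i, j] - bi
    if (bi < 0) { bj <- dd[i, j]; bi <- 0 }
    if (bj < 0) { bi <- dd[i, j]; bj <- 0 }
    merged <- paste0("(", newick[i], ":", fmt(bi), ",",
                     newick[j], ":", fmt(bj), ")")
    d_new <- 0.5 * (dd[i, ] + dd[j, ] - dd[i, j])
    keep <- setdiff(seq_len(r), c(i, j))
    dd <- rbind(cbind(dd[keep, keep, drop = FALSE], d_new[keep]),
                c(d_new[keep], 0))
    newick <- c(newick[keep], merged)
    label <- c(label[keep], min(c(label[i], label[j])))
    rownames(dd) <- colnames(dd) <- label
  }

  b <- c((dd[1, 2] + dd[1, 3] - dd[2, 3]) / 2,
         (dd[1, 2] + dd[2, 3] - dd[1, 3]) / 2,
         (dd[1, 3] + dd[2, 3] - dd[1, 2]) / 2)
  txt <- paste0("(", newick[1], ":", fmt(b[1]), ",",
                newick[2], ":", fmt(b[2]), ",",
                newick[3], ":", fmt(b[3]), ");")
  ape::read.tree(text = txt)
}

#' Write a tree in Newick format
#'
#' Branch lengths with 6 decimals; the unrooted trifurcation of the last
#' join is preserved.
#'
#' @param tree a `phylo` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 6)
  invisible(path)
}

#' Observed heterozygosity per cohort
#'
#' Per sample, the fraction of non-missing genotypes that are
#' heterozygous; the cohort value is the mean over its samples.
#'
#' @param gt a [genotype_table()].
#' @return tibble with columns `cohort`, `heterozygosity`.
#' @export
observed_heterozygosity <- function(gt) {
  per_sample <- rowMeans(gt$dosage == 1L, na.rm = TRUE)
  dplyr::summarise(
    dplyr::group_by(tibble(cohort = gt$samples$cohort, het = per_sample),
                    .data$cohort),
    heterozygosity = mean(.data$het), .groups = "drop"
  )
}
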