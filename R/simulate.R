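#' Simulation configuration
#'
#' Parameters of the synthetic two-cohort study generator.  Defaults
#' mirror the study design the pipeline targets: two cohorts of 7
#' diploid samples, a few thousand loss-of-function (LOF) variants spread
#' over a few hundred genes with Balding-Nichols allele-frequency
#' differentiation between the cohorts, and a ~10,000-gene expression
#' matrix with planted differential expression.
#'
#' @param seed integer seed; every generator call is deterministic given
#'   the config.
#' @param n_per_cohort samples per cohort (7).
#' @param n_genes_variant number of genes carrying LOF variants.
#' @param lof_per_gene mean LOF variants per gene (counts drawn as
#'   `1 + Poisson(lof_per_gene - 1)`, so some genes receive a single
#'   variant and exercise the downstream >= 2 filter).
#' @param n_neutral_variants intergenic/synonymous variants with no gene
#'   assignment.
#' @param fst Balding-Nichols differentiation parameter in `[0, 1)`.
#' @param maf_range interval in `(0, 0.5]` the ancestral minor-allele
#'   frequency is drawn from (uniformly).
#' @param missing_rate per-genotype missingness probability.
#' @param assoc_genes tibble/data frame with columns `gene` (index into
#'   the simulated genes, or id `"gene0001"` style) and `shift`: the
#'   allele-frequency shift added to cohort B for that gene's variants.
#' @param n_genes_expr genes in the expression matrix.
#' @param n_de_genes planted differentially expressed genes.
#' @param de_lfc_mean,de_lfc_sd log2 fold-change magnitude distribution
#'   of the planted DE genes (sign randomised).
#' @param nb_dispersion negative-binomial dispersion of counts
#'   (`variance = mu + dispersion * mu^2`).
#' @param length_range gene effective-length interval (bp).
#'
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_per_cohort = 7L,
                       n_genes_variant = 300L,
                       lof_per_gene = 4,
                       n_neutral_variants = 2000L,
                       fst = 0.1,
                       maf_range = c(0.05, 0.5),
                       missing_rate = 0.02,
                       assoc_genes = NULL,
                       n_genes_expr = 10000L,
                       n_de_genes = 100L,
                       de_lfc_mean = 4,
                       de_lfc_sd = 0.5,
                       nb_dispersion = 0.1,
                       length_range = c(500, 5000)) {
  cfg <- list(
    seed = as.integer(seed), n_per_cohort = as.integer(n_per_cohort),
    n_genes_variant = as.integer(n_genes_variant),
    lof_per_gene = lof_per_gene,
    n_neutral_variants = as.integer(n_neutral_variants),
    fst = fst, maf_range = maf_range, missing_rate = missing_rate,
    assoc_genes = if (is.null(assoc_genes)) {
      tibble(gene = character(), shift = numeric())
    } else {
      as_tibble(assoc_genes)
    },
    n_genes_expr = as.integer(n_genes_expr),
    n_de_genes = as.integer(n_de_genes),
    de_lfc_mean = de_lfc_mean, de_lfc_sd = de_lfc_sd,
    nb_dispersion = nb_dispersion, length_range = length_range
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_per_cohort < 1L || cfg$n_genes_variant < 0L ||
      cfg$n_neutral_variants < 0L || cfg$n_genes_expr < 1L ||
      cfg$n_de_genes < 0L) {
    abort("counts must be non-negative (cohort size and expression genes positive)")
  }
  if (cfg$fst < 0 || cfg$fst >= 1) abort("fst must lie in [0, 1)")
  if (cfg$missing_rate < 0 || cfg$missing_rate > 1) {
    abort("missing_rate must be a probability")
  }
  if (length(cfg$maf_range) != 2L || any(cfg$maf_range <= 0) ||
      any(cfg$maf_range > 0.5) || diff(cfg$maf_range) < 0) {
    abort("maf_range must be an interval within (0, 0.5]")
  }
  if (cfg$lof_per_gene < 1) abort("lof_per_gene must be >= 1")
  if (cfg$n_de_genes > cfg$n_genes_expr) {
    abort("n_de_genes may not exceed n_genes_expr")
  }
  if (cfg$nb_dispersion < 0) abort("nb_dispersion must be >= 0")
  if (length(cfg$length_range) != 2L || any(cfg$length_range <= 0) ||
      diff(cfg$length_range) < 0) {
    abort("length_range must be a positive interval")
  }
  invisible(cfg)
}

#' Simulate two-cohort genotypes under the Balding-Nichols model
#'
#' Each variant draws an ancestral minor-allele frequency `p` uniformly
#' from `maf_range`; with differentiation `F = fst > 0` each cohort draws
#' its own frequency from `Beta(p(1-F)/F, (1-p)(1-F)/F)` (mean `p`,
#' variance `F p (1-p)`); with `F = 0` both cohorts share `p` exactly.
#' Genotypes are `Binomial(2, cohort frequency)`, then masked missing
#' with probability `missing_rate`.  LOF variants are grouped into genes
#' (`gene0001`, ...); genes listed in `assoc_genes` get the configured
#' shift added to their cohort-B allele frequency, clipped to
#' `[0.01, 0.99]`.  Dosages are then oriented to the combined-sample
#' minor allele.
#'
#' @param config a [sim_config()].
#' @return a [genotype_table()].
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_per_cohort

  n_lof_per_gene <- if (config$n_genes_variant > 0) {
    1L + rpois(config$n_genes_variant, config$lof_per_gene - 1)
  } else integer()
  gene_ids <- sprintf("gene%04d", seq_len(config$n_genes_variant))
  gene_of <- rep(gene_ids, n_lof_per_gene)
  m_lof <- length(gene_of)
  m <- m_lof + config$n_neutral_variants
  gene <- c(gene_of, rep(NA_character_, config$n_neutral_variants))
  func_class <- c(rep("stopgain", m_lof),
                  rep("synonymous SNV", config$n_neutral_variants))

  p_anc <- runif(m, config$maf_range[1], config$maf_range[2])
  draw_cohort_freq <- function(p) {
    if (config$fst == 0) return(p)
    f <- config$fst
    rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
  }
  p_a <- draw_cohort_freq(p_anc)
  p_b <- draw_cohort_freq(p_anc)

  shifts <- config$assoc_genes
  if (nrow(shifts) > 0) {
    hit <- match(gene, as.character(shifts$gene))
    idx <- which(!is.na(hit))
    p_b[idx] <- pmin(pmax(p_b[idx] + shifts$shift[hit[idx]], 0.01), 0.99)
  }
  # Keep Bernoulli draws valid in degenerate corners.
  p_a <- pmin(pmax(p_a, 1e-6), 1 - 1e-6)
  p_b <- pmin(pmax(p_b, 1e-6), 1 - 1e-6)

  g_a <- matrix(rbinom(n * m, 2L, rep(p_a, each = n)), nrow = n)
  g_b <- matrix(rbinom(n * m, 2L, rep(p_b, each = n)), nrow = n)
  d <- rbind(g_a, g_b)
  if (config$missing_rate > 0) {
    d[matrix(runif(length(d)) < config$missing_rate, nrow = nrow(d))] <- NA_integer_
  }

  pos <- seq_len(m) * 100L
  variants <- tibble(
    variant_id = sprintf("1:%d:A:G", pos),
    chrom = "1", pos = pos, ref = "A", alt = "G",
    gene = gene, func_class = func_class
  )
  samples <- tibble(
    sample_id = c(sprintf("A%02d", seq_len(n)), sprintf("B%02d", seq_len(n))),
    cohort = rep(c("A", "B"), each = n)
  )
  o <- orient_to_minor(d)
  variants$flipped <- unname(o$flipped)
  genotype_table(o$dosage, samples, variants)
}

#' Simulate a two-cohort expression matrix
#'
#' Per gene, a baseline mean count is drawn log-normally; planted DE
#' genes multiply the cohort-B mean by `2^LFC` with
#' `|LFC| ~ Normal(de_lfc_mean, de_lfc_sd)` and random sign.  Counts are
#' negative binomial with the configured dispersion (a dispersion of 0 is
#' floored at 1e-8, i.e. effectively Poisson); gene lengths are uniform
#' on `length_range`.
#'
#' @param config a [sim_config()].
#' @return an [expression_table()] of counts.
#' @export
simulate_expression <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  g <- config$n_genes_expr
  n <- config$n_per_cohort
  gene_ids <- sprintf("expr%05d", seq_len(g))
  base_mean <- rlnorm(g, meanlog = 4, sdlog = 1)
  lengths <- round(runif(g, config$length_range[1], config$length_range[2]))

  de_idx <- if (config$n_de_genes > 0) {
    sort(sample.int(g, config$n_de_genes))
  } else integer()
  lfc <- numeric(g)
  if (length(de_idx)) {
    lfc[de_idx] <- rnorm(length(de_idx), config$de_lfc_mean, config$de_lfc_sd) *
      sample(c(-1, 1), length(de_idx), replace = TRUE)
  }
  mu_a <- base_mean
  mu_b <- base_mean * 2^lfc
  size <- 1 / max(config$nb_dispersion, 1e-8)
  counts_a <- matrix(rnbinom(g * n, mu = rep(mu_a, n), size = size), nrow = g)
  counts_b <- matrix(rnbinom(g * n, mu = rep(mu_b, n), size = size), nrow = g)
  counts <- cbind(counts_a, counts_b)
  samples <- tibble(
    sample_id = c(sprintf("A%02d", seq_len(n)), sprintf("B%02d", seq_len(n))),
    cohort = rep(c("A", "B"), each = n)
  )
  et <- expression_table(counts,
                         genes = tibble(gene_id = gene_ids, length = lengths),
                         samples = samples, unit = "counts")
  attr(et, "planted_lfc") <- tibble(gene = gene_ids[de_idx], lfc = lfc[de_idx])
  et
}

#' Simulate a full synthetic study
#'
#' Composes [simulate_genotypes()] and [simulate_expression()] and
#' records the planted truth (associated genes and DE genes with their
#' effect sizes).  When `dir` is given, fixture files are written there:
#' a VCF 4.2, annotation/sample/expression TSVs, and a truth JSON (see
#' [write_study()]).
#'
#' @param config a [sim_config()].
#' @param dir optional output directory.
#' @return a `synthetic_study` list: `genotypes`, `expression`, `truth`,
#'   and (when written) `files`.
#' @export
simulate_study <- function(config, dir = NULL) {
  gt <- simulate_genotypes(config)
  et <- simulate_expression(config)
  truth <- list(
    assoc_genes = as_tibble(config$assoc_genes),
    de_genes = attr(et, "planted_lfc")
  )
  stopifnot(all(as.character(truth$assoc_genes$gene) %in% gt$variants$gene |
                  nrow(truth$assoc_genes) == 0))
  study <- structure(
    list(genotypes = gt, expression = et, truth = truth, config = config),
    class = "synthetic_study"
  )
  if (!is.null(dir)) study$files <- write_study(study, dir)
  study
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("<synthetic_study>\n")
  print(x$genotypes)
  cat(sprintf("  expression: %d genes x %d samples (%s)\n",
              nrow(x$expression$values), ncol(x$expression$values),
              x$expression$unit))
  cat(sprintf("  truth: %d planted associated genes, %d planted DE genes\n",
              nrow(x$truth$assoc_genes), nrow(x$truth$de_genes)))
  invisible(x)
}
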