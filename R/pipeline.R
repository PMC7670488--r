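#' Summary interval for a trait
#'
#' The reported interval is `mean +/- SD / sqrt(n)` (one standard
#' error), rounded to 2 decimals.  Note this is a standard-error band,
#' not a t- or z-confidence interval, and it is labelled accordingly in
#' output.
#'
#' @param mean,sd,n summary statistics of the trait.
#' @return named numeric vector `c(low, high)`.
#' @export
trait_interval <- function(mean, sd, n) {
  se <- sd / sqrt(n)
  c(low = round(mean - se, 2), high = round(mean + se, 2))
}

#' Summarise agricultural traits per cohort
#'
#' Per trait and cohort: n, min, max, mean, sample SD, and the
#' mean +/- SE interval of [trait_interval()].  Groups with fewer than
#' 2 observations are skipped with a warning.
#'
#' @param measurements data frame with columns `trait`, `cohort`,
#'   `value`.
#' @return tibble with columns `trait`, `cohort`, `n`, `min`, `max`,
#'   `mean`, `sd`, `interval_low`, `interval_high`.
#' @export
summarize_traits <- function(measurements) {
  m <- as_tibble(measurements)
  stopifnot(all(c("trait", "cohort", "value") %in% names(m)))
  small <- dplyr::count(dplyr::group_by(m, .data$trait, .data$cohort))
  if (any(small$n < 2)) {
    warn("trait x cohort group(s) with fewer than 2 observations skipped")
  }
  out <- dplyr::summarise(
    dplyr::group_by(m, .data$trait, .data$cohort),
    n = dplyr::n(), min = min(.data$value), max = max(.data$value),
    mean = mean(.data$value), sd = sd(.data$value), .groups = "drop"
  )
  out <- out[out$n >= 2, ]
  iv <- purrr::pmap(list(out$mean, out$sd, out$n), trait_interval)
  out$interval_low <- vapply(iv, `[[`, numeric(1), "low")
  out$interval_high <- vapply(iv, `[[`, numeric(1), "high")
  out
}

#' Pipeline configuration
#'
#' Input paths, thresholds and run options for [run_pipeline()].
#' Defaults mirror the standard cascade: call rate 0.90 (strict), MAF
#' 0.01, exact HWE 5e-8 failing in both cohorts, at least 2 LOF variants
#' per gene, alpha 0.05.
#'
#' @param vcf,annotation,samples input file paths (all three required
#'   unless `study` is supplied).
#' @param expression optional expression TSV (gene_id, length, one
#'   column per sample) in counts.
#' @param traits optional trait TSV (trait, cohort, value).
#' @param gene_sets optional GMT file for overrepresentation.
#' @param study optional in-memory `synthetic_study`, used instead of
#'   file inputs.
#' @param out_dir output directory.
#' @param call_rate_min,maf_min,hwe_alpha,min_lof_per_gene QC thresholds.
#' @param alpha significance level.
#' @param outlier_n_sd PCA outlier flagging multiplier.
#' @param remove_outliers drop flagged samples before association
#'   scans (off by default; flagged samples are always reported).
#' @param seed integer seed recorded in the manifest.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(vcf = NULL, annotation = NULL, samples = NULL,
                            expression = NULL, traits = NULL,
                            gene_sets = NULL, study = NULL,
                            out_dir = tempfile("lofassoc_run_"),
                            call_rate_min = 0.90, maf_min = 0.01,
                            hwe_alpha = 5e-8, min_lof_per_gene = 2L,
                            alpha = 0.05, outlier_n_sd = 3,
                            remove_outliers = FALSE, seed = 1L) {
  stopifnot(call_rate_min >= 0, call_rate_min <= 1, maf_min >= 0,
            maf_min <= 0.5, hwe_alpha > 0, hwe_alpha <= 1,
            min_lof_per_gene >= 1, alpha > 0, alpha <= 1, outlier_n_sd >= 0)
  if (is.null(study) && (is.null(vcf) || is.null(annotation) || is.null(samples))) {
    abort("supply either `study` or all of vcf/annotation/samples paths")
  }
  structure(
    list(vcf = vcf, annotation = annotation, samples = samples,
         expression = expression, traits = traits, gene_sets = gene_sets,
         study = study, out_dir = out_dir, call_rate_min = call_rate_min,
         maf_min = maf_min, hwe_alpha = hwe_alpha,
         min_lof_per_gene = as.integer(min_lof_per_gene), alpha = alpha,
         outlier_n_sd = outlier_n_sd, remove_outliers = remove_outliers,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

write_stage_tsv <- function(x, dir, name) {
  path <- file.path(dir, name)
  readr::write_tsv(x, path)
  path
}

#' Run the full two-cohort analysis pipeline
#'
#' Stages: variant QC -> PCA outlier detection (removal opt-in) ->
#' single-variant Fisher scan -> gene-level LOF scan -> population
#' structure (IBS distances, NJ tree, heterozygosity) -> differential
#' expression -> report.  Every stage writes its outputs under
#' `config$out_dir`, and a run manifest JSON records the configuration,
#' seed, package version and MD5 checksum of every output file.  A stage
#' failure aborts with the stage name; outputs of completed stages are
#' retained on disk.
#'
#' @param config a [pipeline_config()].
#' @return a `pipeline_report` list with per-stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  report <- list(config = config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }

  # -- stage 1: read + variant QC ------------------------------------
  qc <- stage("variant_qc", {
    gt <- if (!is.null(config$study)) {
      config$study$genotypes
    } else {
      read_study(config$vcf, config$annotation, config$samples)
    }
    apply_variant_qc(gt, call_rate_min = config$call_rate_min,
                     maf_min = config$maf_min, hwe_alpha = config$hwe_alpha)
  })
  files["qc_ledger"] <- write_stage_tsv(qc$genotypes$ledger, config$out_dir,
                                        "qc_ledger.tsv")
  report$qc <- qc

  # -- stage 2: outlier detection ------------------------------------
  outliers <- stage("outlier_detection", {
    pca <- pca_genotypes(qc$genotypes, k = 2)
    list(pca = pca, flagged = detect_outliers_pca(pca, config$outlier_n_sd))
  })
  files["pca_scores"] <- write_stage_tsv(outliers$pca$scores, config$out_dir,
                                         "pca_scores.tsv")
  report$outliers <- outliers
  gt <- qc$genotypes
  if (config$remove_outliers && length(outliers$flagged)) {
    keep <- !(gt$samples$sample_id %in% outliers$flagged)
    gt <- subset_genotypes(gt, samples = keep)
    report$removed_samples <- outliers$flagged
  }

  # -- stage 3: single-variant scan ----------------------------------
  scan <- stage("single_variant_scan", run_single_variant_scan(gt))
  files["single_variant"] <- write_stage_tsv(scan$results, config$out_dir,
                                             "single_variant_scan.tsv")
  report$single_variant <- scan

  # -- stage 4: gene-level LOF scan ----------------------------------
  gene_scan <- stage("gene_scan", {
    sets <- select_lof_gene_sets(gt, call_rate_min = config$call_rate_min,
                                 min_lof_per_gene = config$min_lof_per_gene)
    if (nrow(sets) == 0) NULL else run_gene_scan(gt, sets, alpha = config$alpha)
  })
  if (!is.null(gene_scan)) {
    files["gene_scan"] <- write_stage_tsv(
      dplyr::select(gene_scan$results, -dplyr::any_of("variant_ids")),
      config$out_dir, "gene_scan.tsv")
  }
  report$gene_scan <- gene_scan

  # -- stage 5: population structure ---------------------------------
  popstruct <- stage("population_structure", {
    dmat <- ibs_distance(gt)
    tree <- neighbor_joining(dmat)
    het <- observed_heterozygosity(gt)
    list(distance = dmat, tree = tree, heterozygosity = het)
  })
  files["ibs_distance"] <- write_stage_tsv(
    as_tibble(popstruct$distance, rownames = "sample_id"),
    config$out_dir, "ibs_distance.tsv")
  files["nj_tree"] <- write_newick(popstruct$tree,
                                   file.path(config$out_dir, "nj_tree.nwk"))
  files["heterozygosity"] <- write_stage_tsv(popstruct$heterozygosity,
                                             config$out_dir,
                                             "heterozygosity.tsv")
  report$popstructure <- popstruct

  # -- stage 6: differential expression ------------------------------
  de <- stage("differential_expression", {
    expr <- if (!is.null(config$study)) {
      config$study$expression
    } else if (!is.null(config$expression)) {
      read_expression_tsv(config$expression, gt$samples)
    } else NULL
    if (is.null(expr)) return(NULL)
    res <- run_de(expr, alpha = config$alpha)
    ora <- if (!is.null(config$gene_sets)) {
      sets <- read_gmt(config$gene_sets)
      ora_hypergeometric(res$gene[res$significant], res$gene, sets)
    } else NULL
    list(de = res, ora = ora)
  })
  if (!is.null(de)) {
    files["de_results"] <- write_stage_tsv(as_tibble(de$de), config$out_dir,
                                           "de_results.tsv")
    if (!is.null(de$ora)) {
      files["ora"] <- write_stage_tsv(de$ora, config$out_dir, "ora.tsv")
    }
  }
  report$de <- de

  # -- stage 7: report + manifest ------------------------------------
  manifest <- stage("report", {
    if (!is.null(config$traits)) {
      tr <- readr::read_tsv(config$traits, show_col_types = FALSE)
      report$traits <- summarize_traits(tr)
      files["trait_summary"] <- write_stage_tsv(report$traits,
                                                 config$out_dir,
                                                 "trait_summary.tsv")
    }
    cfg <- config
    cfg$study <- NULL  # not serialisable; inputs are recorded via checksums
    man <- list(
      package = "lofassoc",
      version = as.character(utils::packageVersion("lofassoc")),
      seed = config$seed,
      stages = c("variant_qc", "outlier_detection", "single_variant_scan",
                 "gene_scan", "population_structure",
                 "differential_expression", "report"),
      config = cfg[!vapply(cfg, is.null, logical(1))],
      files = as.list(unname(tools::md5sum(files))) |>
        setNames(basename(files))
    )
    path <- file.path(config$out_dir, "manifest.json")
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA)
    man
  })
  report$manifest <- manifest
  class(report) <- "pipeline_report"
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat("  stages:", paste(x$manifest$stages, collapse = ", "), "\n")
  cat("  outputs in:", x$config$out_dir, "\n")
  invisible(x)
}

#' Read an expression TSV
#'
#' Columns: `gene_id`, `length`, then one count column per sample.
#'
#' @param path TSV path.
#' @param samples sample sheet tibble (`sample_id`, `cohort`).
#' @return an [expression_table()] of counts.
#' @export
read_expression_tsv <- function(path, samples) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("gene_id", "length") %in% names(df)))
  sample_cols <- setdiff(names(df), c("gene_id", "length"))
  samples <- as_tibble(samples)
  missing <- setdiff(sample_cols, samples$sample_id)
  if (length(missing)) {
    abort(paste0("expression sample(s) not in sample sheet: ",
                 paste(missing, collapse = ", ")))
  }
  expression_table(as.matrix(df[, sample_cols]),
                   genes = df[, c("gene_id", "length")],
                   samples = samples[match(sample_cols, samples$sample_id), ],
                   unit = "counts")
}
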