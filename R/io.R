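#' Write a genotype table as VCF 4.2
#'
#' Emits biallelic SNP records with a GT field and 1-based positions.
#' Genotypes are written relative to REF/ALT (minor-allele orientation is
#' undone), so the file round-trips through [read_study()].
#'
#' @param gt a [genotype_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(gt, path) {
  d <- alt_dosage(gt)
  gt_code <- matrix("./.", nrow = nrow(d), ncol = ncol(d))
  gt_code[!is.na(d) & d == 0L] <- "0/0"
  gt_code[!is.na(d) & d == 1L] <- "0/1"
  gt_code[!is.na(d) & d == 2L] <- "1/1"
  v <- gt$variants
  body <- cbind(v$chrom, v$pos, v$variant_id, v$ref, v$alt, ".", "PASS", ".",
                "GT", t(gt_code))
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=lofassoc",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste0("##contig=<ID=", unique(v$chrom), ">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gt$samples$sample_id), collapse = "\t"),
    apply(body, 1, paste, collapse = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write all fixture files of a synthetic study
#'
#' Writes `genotypes.vcf`, `annotation.tsv` (variant_id, gene,
#' func_class), `samples.tsv` (sample_id, cohort), `expression.tsv`
#' (gene_id, length, one column per sample) and `truth.json`.
#'
#' @param study a `synthetic_study` from [simulate_study()].
#' @param dir output directory (created if needed).
#' @return named character vector of file paths.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    vcf = file.path(dir, "genotypes.vcf"),
    annotation = file.path(dir, "annotation.tsv"),
    samples = file.path(dir, "samples.tsv"),
    expression = file.path(dir, "expression.tsv"),
    truth = file.path(dir, "truth.json")
  )
  ok <- tryCatch({
    write_genotypes_vcf(study$genotypes, paths["vcf"])
    ann <- dplyr::filter(study$genotypes$variants, !is.na(.data$gene))
    readr::write_tsv(ann[, c("variant_id", "gene", "func_class")],
                     paths["annotation"])
    readr::write_tsv(study$genotypes$samples, paths["samples"])
    expr <- study$expression
    expr_df <- dplyr::bind_cols(expr$genes, as_tibble(expr$values))
    readr::write_tsv(expr_df, paths["expression"])
    jsonlite::write_json(
      list(assoc_genes = study$truth$assoc_genes,
           de_genes = study$truth$de_genes),
      paths["truth"], digits = NA
    )
    TRUE
  }, error = function(e) {
    abort(paste0("failed writing study fixtures under '", dir, "': ",
                 conditionMessage(e)))
  })
  stopifnot(isTRUE(ok))
  paths
}

#' Read a two-cohort genotype study
#'
#' Reads a VCF (GT field), a variant annotation TSV (`variant_id` as
#' `chrom:pos:ref:alt`, `gene`, `func_class`) and a sample TSV
#' (`sample_id`, `cohort`).  Multiallelic records are dropped and logged
#' in the table's ledger.  Dosages are oriented to the combined-sample
#' minor allele; variants annotated to more than one gene get `gene = NA`
#' with `multi_gene = TRUE` so that gene-level selection can exclude
#' them.
#'
#' @param vcf_path,annotation_path,samples_path input file paths.
#' @return a [genotype_table()] whose `ledger` records the multiallelic
#'   removal step.
#' @export
read_study <- function(vcf_path, annotation_path, samples_path) {
  for (p in c(vcf_path, annotation_path, samples_path)) {
    if (!file.exists(p)) abort(paste0("file not found: ", p))
  }
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  samples <- readr::read_tsv(samples_path, show_col_types = FALSE)
  if (!all(c("sample_id", "cohort") %in% names(samples))) {
    abort("samples TSV needs columns sample_id, cohort")
  }
  vcf_samples <- colnames(gt_raw)
  unknown <- setdiff(vcf_samples, samples$sample_id)
  if (length(unknown)) {
    abort(paste0("VCF sample(s) not in sample sheet: ",
                 paste(unknown, collapse = ", ")))
  }
  samples <- samples[match(vcf_samples, samples$sample_id), ]

  multi <- grepl(",", fix$ALT) | is.na(fix$ALT)
  n_in <- nrow(fix)
  fix <- fix[!multi, , drop = FALSE]
  gt_raw <- gt_raw[!multi, , drop = FALSE]

  parse_gt <- function(x) {
    # GT strings like 0/0, 0|1, ./.; anything unparsable is an error.
    out <- rep(NA_integer_, length(x))
    known <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
               "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L)
    miss <- is.na(x) | x %in% c("./.", ".|.", ".")
    idx <- !miss
    mapped <- known[x[idx]]
    if (anyNA(mapped)) {
      bad <- which(idx)[which(is.na(mapped))[1]]
      abort(paste0("malformed GT at VCF record ", bad, ": '", x[bad], "'"))
    }
    out[idx] <- mapped
    out
  }
  d_alt <- vapply(seq_along(vcf_samples), function(j) parse_gt(gt_raw[, j]),
                  integer(nrow(gt_raw)))
  if (is.null(dim(d_alt))) d_alt <- matrix(d_alt, nrow = 1L)
  # variants x samples -> samples x variants
  d_alt <- t(matrix(d_alt, nrow = nrow(gt_raw)))

  vid <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste(fix$CHROM, fix$POS, fix$REF, fix$ALT, sep = ":"),
                fix$ID)
  ann <- readr::read_tsv(annotation_path, show_col_types = FALSE)
  if (!all(c("variant_id", "gene", "func_class") %in% names(ann))) {
    abort("annotation TSV needs columns variant_id, gene, func_class")
  }
  ann_gene <- dplyr::summarise(
    dplyr::group_by(ann, .data$variant_id),
    n_genes = dplyr::n_distinct(.data$gene),
    gene = .data$gene[1],
    func_class = .data$func_class[1],
    .groups = "drop"
  )
  hit <- match(vid, ann_gene$variant_id)
  gene <- ann_gene$gene[hit]
  func_class <- ann_gene$func_class[hit]
  multi_gene <- !is.na(hit) & ann_gene$n_genes[hit] > 1L
  gene[multi_gene] <- NA_character_

  o <- orient_to_minor(d_alt)
  variants <- tibble(
    variant_id = vid, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, gene = gene,
    func_class = ifelse(is.na(func_class), "unannotated", func_class),
    flipped = unname(o$flipped), multi_gene = multi_gene
  )
  ledger <- qc_ledger("multiallelic", n_in, sum(multi))
  genotype_table(o$dosage, samples[, c("sample_id", "cohort")], variants,
                 ledger = ledger)
}

#' Read a GMT gene-set file
#'
#' Tab-separated: set name, description, then member genes.
#'
#' @param path GMT file path.
#' @return named list of character vectors of member genes.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) abort(paste0("GMT line ", which(bad)[1], " has fewer than 3 fields"))
  setNames(lapply(parts, function(x) unique(x[-(1:2)])),
           vapply(parts, `[[`, "", 1L))
}
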