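#' Read a pedigree from CSV/TSV
#'
#' The file must carry animal, sire and dam columns (comma- or tab-separated,
#' header required). Unknown parents may be coded 0, empty, or NA. Rows may
#' appear in any order; the returned pedigree is topologically sorted.
#'
#' @param path file path.
#' @param id_columns names of the animal, sire and dam columns, in that
#'   order.
#' @return A [pedigree()].
#' @export
read_pedigree <- function(path, id_columns = c("animal", "sire", "dam")) {
  df <- read_delim_auto(path)
  miss <- setdiff(id_columns, names(df))
  if (length(miss))
    stop("pedigree file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  pedigree(df[[id_columns[1]]], df[[id_columns[2]]], df[[id_columns[3]]])
}

read_delim_auto <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, colClasses = "character",
                    na.strings = c("NA", ""))
}

#' Read biallelic genotypes from a VCF
#'
#' Parses the GT field of a VCF (plain text or bgzipped) into an ALT-dosage
#' [genotype_matrix()]. Multi-allelic records are skipped with a logged
#' count; records on contigs that are not autosomes or sex chromosomes
#' (scaffolds, mitochondrion) are dropped.
#'
#' @param path VCF file path.
#' @param exclude_contigs regular expression matched (case-insensitively)
#'   against contig names; matching records are removed.
#' @return A [genotype_matrix()] with attribute `n_multiallelic_skipped`.
#' @export
read_genotypes_vcf <- function(path,
                               exclude_contigs = "scaffold|^chrM|^MT?$|mito") {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  if (ncol(vcf) == 0L) stop("VCF has no samples", call. = FALSE)
  rr <- SummarizedExperiment::rowRanges(vcf)
  n_alt <- S4Vectors::elementNROWS(VariantAnnotation::alt(vcf))
  multi <- n_alt > 1L
  if (any(multi))
    message(sprintf("read_genotypes_vcf: skipped %d multi-allelic record(s)",
                    sum(multi)))
  chrom <- as.character(GenomicRanges::seqnames(rr))
  drop_contig <- grepl(exclude_contigs, chrom, ignore.case = TRUE)
  if (any(drop_contig))
    message(sprintf(
      "read_genotypes_vcf: excluded %d record(s) on scaffold/mitochondrial contigs",
      sum(drop_contig)))
  keep <- !multi & !drop_contig
  if (!any(keep)) stop("no usable biallelic records in VCF", call. = FALSE)
  gt <- VariantAnnotation::geno(vcf)$GT[keep, , drop = FALSE]
  dos <- matrix(NA_real_, nrow(gt), ncol(gt))
  clean <- gsub("\\|", "/", gt)
  dos[clean %in% c("0/0")] <- 0
  dos[clean %in% c("0/1", "1/0")] <- 1
  dos[clean %in% c("1/1")] <- 2
  g <- genotype_matrix(t(dos),
                       chrom = chrom[keep],
                       pos = GenomicRanges::start(rr)[keep],
                       snp_id = rownames(gt),
                       animal_ids = colnames(gt))
  attr(g, "n_multiallelic_skipped") <- sum(multi)
  g
}

#' Write a minimal GT-only VCF
#'
#' Writes dosages back to VCF 4.2 with placeholder REF/ALT alleles (A/B) and
#' genotypes 0/0, 0/1, 1/1 or ./. . Used by the simulator so a synthetic
#' dataset can be round-tripped through the standard reader.
#'
#' @param g a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s>", unique(g$map$chrom)),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", g$animal_ids), collapse = "\t"), con)
  code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  for (j in seq_len(n_snps(g))) {
    calls <- ifelse(is.na(g$dos[, j]), "./.",
                    code[as.character(g$dos[, j])])
    writeLines(paste(c(g$map$chrom[j], format(g$map$pos[j], scientific = FALSE),
                       g$map$id[j], "A", "B", ".", "PASS", ".", "GT", calls),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a phenotype table from CSV
#'
#' Rows with a missing trait value or any missing model term are dropped and
#' counted; every remaining animal must appear in the pedigree.
#'
#' @param path CSV/TSV file with an animal id column, the trait column, and
#'   the model-term columns.
#' @param trait trait column name.
#' @param fixed_factors,covariates model-term column names.
#' @param ped a [pedigree()] used to validate animal ids.
#' @param id_column animal id column name.
#' @return A [phenotype_table()] with attribute `n_dropped`.
#' @export
read_phenotypes <- function(path, trait, fixed_factors = character(),
                            covariates = character(), ped,
                            id_column = "animal") {
  df <- read_delim_auto(path)
  need <- c(id_column, trait, fixed_factors, covariates)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("phenotype file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df[[trait]] <- suppressWarnings(as.numeric(df[[trait]]))
  for (cv in covariates)
    df[[cv]] <- suppressWarnings(as.numeric(df[[cv]]))
  complete <- stats::complete.cases(df[, need, drop = FALSE])
  n_dropped <- sum(!complete)
  if (n_dropped)
    message(sprintf("read_phenotypes: dropped %d incomplete record(s)",
                    n_dropped))
  df <- df[complete, , drop = FALSE]
  if (!nrow(df))
    stop("no usable phenotype records after dropping incomplete rows",
         call. = FALSE)
  unknown <- setdiff(df[[id_column]], ped$id)
  if (length(unknown))
    stop("phenotyped animal(s) not in pedigree: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  ph <- phenotype_table(df[[id_column]], df[[trait]],
                        factors = df[fixed_factors],
                        covariates = df[covariates], trait = trait)
  attr(ph, "n_dropped") <- n_dropped
  ph
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Write WssGWAS results to TSV files
#'
#' Emits `snp_effects.tsv` (per-SNP effect and weight), `windows.tsv`,
#' `regions.tsv` (windows above the threshold), `varcomp.tsv` and
#' `manhattan.tsv` (plot-ready window table).
#'
#' @param effects named SNP effect vector.
#' @param weights marker weights aligned with `effects`.
#' @param map SNP map aligned with `effects`.
#' @param windows a [window_variances()] table.
#' @param regions a [select_regions()] table.
#' @param vc a `wss_varcomp`.
#' @param out_dir output directory (created if absent).
#' @return Named character vector of file paths, invisibly.
#' @export
write_results <- function(effects, weights, map, windows, regions, vc,
                          out_dir) {
  if (!dir.exists(out_dir))
    if (!dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create output directory: ", out_dir, call. = FALSE)
  paths <- c(
    snp_effects = write_tsv(
      data.frame(snp = map$id, chrom = map$chrom, pos = map$pos,
                 u_hat = unname(effects), weight = unname(weights)),
      file.path(out_dir, "snp_effects.tsv")),
    windows = write_tsv(as.data.frame(windows),
                        file.path(out_dir, "windows.tsv")),
    regions = write_tsv(as.data.frame(regions),
                        file.path(out_dir, "regions.tsv")),
    varcomp = write_tsv(
      data.frame(sigma2_u = vc$sigma2_u, sigma2_e = vc$sigma2_e, h2 = vc$h2,
                 se_h2 = vc$se_h2, n_iter = vc$n_iter, loglik = vc$loglik,
                 converged = vc$converged),
      file.path(out_dir, "varcomp.tsv")),
    manhattan = write_tsv(manhattan_table(windows),
                          file.path(out_dir, "manhattan.tsv"))
  )
  invisible(paths)
}
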