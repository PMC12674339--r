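#' Construct a genotype matrix
#'
#' Holds ALT-allele dosages (0/1/2, `NA` = missing call) for animals x SNPs
#' together with the SNP map. Columns are sorted by (chromosome, position);
#' chromosome order follows first appearance unless labels are numeric-like,
#' in which case natural numeric order is used.
#'
#' @param dosages numeric matrix, animals in rows, SNPs in columns; entries in
#'   \{0, 1, 2, NA\}.
#' @param chrom,pos chromosome label and 1-based bp position per SNP.
#' @param snp_id optional SNP names; defaults to `chrom_pos`.
#' @param animal_ids optional animal labels; defaults to rownames.
#' @return Object of class `wss_genotypes`: list with `dos`, `map`
#'   (data.frame chrom/pos/id) and `animal_ids`.
#' @export
genotype_matrix <- function(dosages, chrom, pos, snp_id = NULL,
                            animal_ids = NULL) {
  dosages <- as.matrix(dosages)
  m <- ncol(dosages)
  if (length(chrom) != m || length(pos) != m)
    stop("chrom/pos length must match the number of SNP columns",
         call. = FALSE)
  ok <- dosages %in% c(0, 1, 2) | is.na(dosages)
  if (!all(ok))
    stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  chrom <- as.character(chrom)
  pos <- as.numeric(pos)
  if (is.null(snp_id)) snp_id <- paste(chrom, pos, sep = "_")
  if (is.null(animal_ids)) animal_ids <- rownames(dosages)
  if (is.null(animal_ids)) animal_ids <- paste0("ind", seq_len(nrow(dosages)))

  suppressWarnings(num <- as.numeric(chrom))
  chrom_lev <- if (!anyNA(num)) as.character(sort(unique(num)))
               else unique(chrom)
  o <- order(match(chrom, chrom_lev), pos)
  g <- list(
    dos = dosages[, o, drop = FALSE],
    map = data.frame(chrom = chrom[o], pos = pos[o], id = as.character(snp_id)[o],
                     stringsAsFactors = FALSE),
    animal_ids = as.character(animal_ids)
  )
  rownames(g$dos) <- g$animal_ids
  colnames(g$dos) <- g$map$id
  class(g) <- "wss_genotypes"
  g
}

#' @export
print.wss_genotypes <- function(x, ...) {
  cat(sprintf("Genotypes: %d animals x %d SNPs on %d chromosome(s); %.2f%% missing\n",
              nrow(x$dos), ncol(x$dos), length(unique(x$map$chrom)),
              100 * mean(is.na(x$dos))))
  invisible(x)
}

n_snps <- function(g) ncol(g$dos)
n_animals <- function(g) nrow(g$dos)

#' Observed ALT allele frequencies
#'
#' Per-SNP frequency of the counted (ALT) allele, from non-missing calls only.
#'
#' @param g a [genotype_matrix()].
#' @return Named numeric vector `p`; the REF frequency is `1 - p`.
#' @export
allele_frequencies <- function(g) {
  p <- colMeans(g$dos, na.rm = TRUE) / 2
  p[is.nan(p)] <- NA_real_
  p
}

qc_step <- function(criterion, removed, n_removed, n_remaining) {
  list(criterion = criterion, removed = removed,
       n_removed = n_removed, n_remaining = n_remaining)
}

qc_result <- function(g, step) {
  message(sprintf("QC [%s]: removed %d, %d remaining",
                  step$criterion, step$n_removed, step$n_remaining))
  structure(list(genotypes = g, report = list(step)), class = "wss_qc")
}

drop_snps <- function(g, keep) {
  g$dos <- g$dos[, keep, drop = FALSE]
  g$map <- g$map[keep, , drop = FALSE]
  rownames(g$map) <- NULL
  g
}

#' SNP call-rate filter
#'
#' Removes SNPs whose fraction of non-missing calls is below `min_rate`.
#'
#' @param g a [genotype_matrix()].
#' @param min_rate minimum call rate in \[0, 1\].
#' @return List with `genotypes` (filtered) and `report`.
#' @export
filter_call_rate <- function(g, min_rate) {
  cr <- colMeans(!is.na(g$dos))
  keep <- cr >= min_rate
  qc_result(drop_snps(g, keep),
            qc_step("call_rate", g$map$id[!keep], sum(!keep), sum(keep)))
}

#' Minor allele frequency filter
#'
#' Removes SNPs with min(p, 1 - p) below `maf_min`, frequencies taken over
#' current non-missing calls (monomorphic SNPs always fail for maf_min > 0).
#'
#' @inheritParams filter_call_rate
#' @param maf_min minimum minor allele frequency.
#' @return List with `genotypes` and `report`.
#' @export
filter_maf <- function(g, maf_min) {
  p <- allele_frequencies(g)
  maf <- pmin(p, 1 - p)
  keep <- !is.na(maf) & maf >= maf_min
  qc_result(drop_snps(g, keep),
            qc_step("maf", g$map$id[!keep], sum(!keep), sum(keep)))
}

#' Hardy-Weinberg equilibrium filter
#'
#' One-degree-of-freedom chi-square goodness of fit of observed genotype
#' counts against (q^2, 2pq, p^2) expectations on non-missing calls, without
#' continuity correction; SNPs with p-value below `alpha` are removed.
#'
#' @inheritParams filter_call_rate
#' @param alpha p-value cutoff (e.g. 1e-6).
#' @return List with `genotypes` and `report`.
#' @export
filter_hwe <- function(g, alpha) {
  pv <- hwe_pvalues(g)
  keep <- is.na(pv) | pv >= alpha
  qc_result(drop_snps(g, keep),
            qc_step("hwe", g$map$id[!keep], sum(!keep), sum(keep)))
}

hwe_pvalues <- function(g) {
  d <- g$dos
  n0 <- colSums(d == 0, na.rm = TRUE)
  n1 <- colSums(d == 1, na.rm = TRUE)
  n2 <- colSums(d == 2, na.rm = TRUE)
  n <- n0 + n1 + n2
  p <- (2 * n2 + n1) / (2 * n)
  exp0 <- n * (1 - p)^2
  exp1 <- n * 2 * p * (1 - p)
  exp2 <- n * p^2
  chi <- numeric(length(n))
  for (k in 1:3) {
    obs <- switch(k, n0, n1, n2)
    ex <- switch(k, exp0, exp1, exp2)
    term <- ifelse(ex > 0, (obs - ex)^2 / ex, 0)
    chi <- chi + term
  }
  pv <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
  pv[n == 0] <- NA_real_
  pv
}

#' Mendelian (parent-progeny) conflict filter
#'
#' A conflict is an opposing-homozygote pair (parent 0 with child 2 or parent
#' 2 with child 0) at a SNP where both calls are non-missing; heterozygous
#' parents can never conflict. Animals whose conflict fraction over checkable
#' (animal, parent, SNP) comparisons exceeds `max_fraction` are removed
#' (their genotype rows are dropped).
#'
#' @inheritParams filter_call_rate
#' @param ped a [pedigree()] linking genotyped animals to their parents.
#' @param max_fraction maximum tolerated conflict fraction per animal.
#' @return List with `genotypes` and `report`.
#' @export
filter_mendel_conflicts <- function(g, ped, max_fraction) {
  idx <- match(g$animal_ids, ped$id)
  if (anyNA(idx))
    stop("genotyped animal(s) not in pedigree: ",
         paste(g$animal_ids[is.na(idx)], collapse = ", "), call. = FALSE)
  row_of <- match(ped$id, g$animal_ids)  # pedigree position -> genotype row
  conf <- chk <- numeric(n_animals(g))
  for (r in seq_len(n_animals(g))) {
    i <- idx[r]
    for (p in c(ped$sire[i], ped$dam[i])) {
      if (is.na(p)) next
      pr <- row_of[p]
      if (is.na(pr)) next
      a <- g$dos[r, ]
      b <- g$dos[pr, ]
      both <- !is.na(a) & !is.na(b)
      conf[r] <- conf[r] + sum(both & abs(a - b) == 2)
      chk[r] <- chk[r] + sum(both)
    }
  }
  frac <- ifelse(chk > 0, conf / chk, 0)
  keep <- frac <= max_fraction
  removed <- g$animal_ids[!keep]
  g$dos <- g$dos[keep, , drop = FALSE]
  g$animal_ids <- g$animal_ids[keep]
  qc_result(g, qc_step("mendel_conflicts", removed,
                       length(removed), sum(keep)))
}

#' Greedy LD pruning
#'
#' Within sliding windows of `window` SNPs advanced by `step` (per
#' chromosome, map order), the later SNP of any pair whose squared Pearson
#' correlation of dosages exceeds `r2_max` is removed. At `r2_max = 1` only
#' perfect duplicates (r^2 numerically 1) are removed.
#'
#' @inheritParams filter_call_rate
#' @param r2_max squared correlation threshold in (0, 1].
#' @param window,step window length and advance, in SNPs.
#' @return List with `genotypes` and `report`.
#' @export
ld_prune <- function(g, r2_max, window = 50L, step = 5L) {
  thr <- if (r2_max >= 1) 1 - 1e-9 else r2_max
  keep <- rep(TRUE, n_snps(g))
  for (ch in unique(g$map$chrom)) {
    snps <- which(g$map$chrom == ch)
    start <- 1L
    while (start <= length(snps)) {
      live <- snps[keep[snps]]
      win <- live[live >= snps[start]]
      win <- win[seq_len(min(window, length(win)))]
      if (length(win) > 1L) {
        cc <- suppressWarnings(
          stats::cor(g$dos[, win, drop = FALSE],
                     use = "pairwise.complete.obs"))
        r2 <- cc^2
        r2[is.na(r2)] <- 0
        for (a in seq_len(length(win) - 1L)) {
          if (!keep[win[a]]) next
          hits <- which(r2[a, ] > thr)
          hits <- hits[hits > a]
          keep[win[hits]] <- FALSE
        }
      }
      start <- start + step
    }
  }
  qc_result(drop_snps(g, keep),
            qc_step("ld_prune", g$map$id[!keep], sum(!keep), sum(keep)))
}

#' Naive mean-dosage imputation
#'
#' Replaces each missing call by the SNP's mean dosage 2p rounded to the
#' nearest integer in \{0, 1, 2\}. A deterministic stand-in for
#' haplotype-based imputation; apply the call-rate filter first so every SNP
#' has observed calls.
#'
#' @inheritParams filter_call_rate
#' @return A [genotype_matrix()] without missing entries.
#' @export
impute_naive <- function(g) {
  p <- allele_frequencies(g)
  if (anyNA(p))
    stop("SNP(s) with no non-missing calls; run filter_call_rate first",
         call. = FALSE)
  fill <- pmin(2, pmax(0, round(2 * p)))
  miss <- which(is.na(g$dos), arr.ind = TRUE)
  if (nrow(miss)) g$dos[miss] <- fill[miss[, 2L]]
  g
}

#' Allele-frequency-centered marker matrix Z
#'
#' Z_ij = dosage_ij - 2 p_j. With frequencies observed from the same data the
#' columns of Z have exactly zero mean.
#'
#' @inheritParams filter_call_rate
#' @param p per-SNP ALT frequencies; defaults to observed frequencies.
#' @return Dense numeric matrix, animals x SNPs.
#' @export
center_matrix <- function(g, p = NULL) {
  if (anyNA(g$dos))
    stop("missing genotypes present; impute before centering", call. = FALSE)
  if (is.null(p)) p <- allele_frequencies(g)
  if (length(p) != n_snps(g)) stop("frequency length mismatch", call. = FALSE)
  sweep(g$dos, 2L, 2 * p)
}

#' Full genotype quality-control pipeline
#'
#' Fixed order: call rate, Mendelian conflicts (animal removal), MAF, HWE,
#' LD pruning, then naive imputation. Frequencies are recomputed inside each
#' step, so SNP filters always see the post-animal-removal data.
#'
#' @param g a [genotype_matrix()].
#' @param ped a [pedigree()].
#' @param config a [run_config()].
#' @return List with `genotypes` (imputed, filter-passing), `freqs` (observed
#'   ALT frequencies after QC) and `report` (a `wss_qc_report` data frame with
#'   per-criterion removal counts; removed ids in `attr(,"removed")`).
#' @export
run_qc <- function(g, ped, config = run_config()) {
  steps <- list()
  push <- function(res) {
    steps[[length(steps) + 1L]] <<- res$report[[1L]]
    res$genotypes
  }
  g <- push(filter_call_rate(g, config$call_rate_min))
  g <- push(filter_mendel_conflicts(g, ped, config$mendel_conflict_max))
  g <- push(filter_maf(g, config$maf_min))
  g <- push(filter_hwe(g, config$hwe_alpha))
  g <- push(ld_prune(g, config$ld_r2_max, config$ld_window, config$ld_step))
  g <- impute_naive(g)
  report <- data.frame(
    criterion = vapply(steps, `[[`, "", "criterion"),
    n_removed = vapply(steps, `[[`, 0, "n_removed"),
    n_remaining = vapply(steps, `[[`, 0, "n_remaining")
  )
  attr(report, "removed") <- lapply(steps, `[[`, "removed")
  class(report) <- c("wss_qc_report", "data.frame")
  list(genotypes = g, freqs = allele_frequencies(g), report = report)
}
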