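test_that("genotype_matrix sorts the map and validates dosages", {
  g <- genotype_matrix(matrix(c(0, 1, 2, 2, 1, 0), 3, 2),
                       chrom = c(2, 1), pos = c(500, 900))
  expect_equal(g$map$chrom, c("1", "2"))
  expect_equal(g$dos[, 1], c(ind1 = 2, ind2 = 1, ind3 = 0))
  expect_error(genotype_matrix(matrix(3, 1, 1), 1, 1), "dosages")
})

test_that("call-rate filter removes SNPs below the threshold", {
  d20 <- function(n_miss) c(rep(NA, n_miss), rep(1, 20 - n_miss))
  g <- toy_genotypes(list(d20(1), d20(3), d20(20)))
  res <- suppressMessages(filter_call_rate(g, 0.90))
  expect_equal(n_snps(res$genotypes), 1L)     # 19/20 kept; 17/20 and 0/20 removed
  expect_equal(res$report[[1]]$n_removed, 2)
})

test_that("MAF filter removes monomorphic and rare SNPs", {
  # p = 0.04: 4 ALT alleles among 100 (2 hets + 1 hom alt + 47 hom ref... use dosage counts)
  rare <- c(rep(1, 4), rep(0, 46))           # p = 0.04 in 50 animals
  g <- toy_genotypes(list(rep(0, 50), rep(1, 50), rare))
  res <- suppressMessages(filter_maf(g, 0.05))
  expect_equal(n_snps(res$genotypes), 1L)
  expect_equal(allele_frequencies(res$genotypes)[[1]], 0.5)
})

test_that("HWE chi-square filter matches hand-computed statistics", {
  counts_col <- function(n0, n1, n2) c(rep(0, n0), rep(1, n1), rep(2, n2))
  g <- toy_genotypes(list(
    counts_col(25, 50, 25),   # chi2 = 0
    counts_col(50, 0, 50),    # chi2 = 100, p << 1e-6
    counts_col(30, 40, 30)))  # chi2 = 4,  p ~ 0.0455
  pv <- unname(wssgwas:::hwe_pvalues(g))
  expect_equal(pv[1], 1)
  expect_equal(pv[3], pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-12)
  res <- suppressMessages(filter_hwe(g, 1e-6))
  expect_equal(n_snps(res$genotypes), 2L)
  expect_equal(res$report[[1]]$removed, g$map$id[2])
})

test_that("Mendelian conflict filter counts opposing homozygotes only", {
  ped <- trio_ped()
  # 20 SNPs: parent s homozygous ALT everywhere; child o opposes at 2 SNPs
  m <- 20
  dos <- rbind(s = rep(2, m), d = rep(1, m), o = c(rep(0, 2), rep(2, m - 2)))
  g <- genotype_matrix(dos, rep(1, m), seq_len(m))
  # o opposes the homozygous sire at 2 of 40 checkable comparisons (5%);
  # the heterozygous dam can never conflict
  res <- suppressMessages(filter_mendel_conflicts(g, ped, 0.04))
  expect_equal(res$report[[1]]$removed, "o")
  res2 <- suppressMessages(filter_mendel_conflicts(g, ped, 0.05))
  expect_equal(res2$report[[1]]$n_removed, 0)  # threshold is strict
})

test_that("LD pruning drops later duplicates and spares independent SNPs", {
  set.seed(1)
  x <- rbinom(200, 2, 0.4)
  g <- toy_genotypes(list(x, rbinom(200, 2, 0.4), x))
  res <- suppressMessages(ld_prune(g, 0.99, window = 10, step = 2))
  expect_equal(res$report[[1]]$removed, g$map$id[3])

  g2 <- hwe_genotypes(200, 30)
  res2 <- suppressMessages(ld_prune(g2, 0.99, window = 10, step = 2))
  expect_equal(res2$report[[1]]$n_removed, 0)

  # r2_max = 1 removes duplicates but never noisy pairs
  res3 <- suppressMessages(ld_prune(g, 1.0, window = 10, step = 2))
  expect_equal(res3$report[[1]]$removed, g$map$id[3])
  res4 <- suppressMessages(ld_prune(g2, 1.0, window = 10, step = 2))
  expect_equal(res4$report[[1]]$n_removed, 0)
})

test_that("naive imputation fills missing with rounded 2p and nothing else", {
  g <- toy_genotypes(list(c(0, 2, NA), c(2, 2, NA), c(0, 1, 2)))
  imp <- impute_naive(g)
  expect_equal(unname(imp$dos[3, ]), c(1, 2, 2))
  expect_equal(imp$dos[1:2, ], g$dos[1:2, ])
  expect_false(anyNA(imp$dos))

  g_all_na <- toy_genotypes(list(c(NA, NA, NA)))
  expect_error(impute_naive(g_all_na), "filter_call_rate")
})

test_that("center_matrix subtracts 2p and errors on missing data", {
  g <- toy_genotypes(list(c(0, 1, 2)))
  expect_equal(unname(center_matrix(g)[, 1]), c(-1, 0, 1))
  expect_equal(unname(center_matrix(g, p = 0)[, 1]), c(0, 1, 2))
  set.seed(2)
  g2 <- hwe_genotypes(50, 10)
  expect_equal(max(abs(colMeans(center_matrix(g2)))), 0, tolerance = 1e-12)
  g3 <- toy_genotypes(list(c(0, NA, 2)))
  expect_error(center_matrix(g3), "missing")
})

test_that("run_qc applies filters in the documented order with exact counts", {
  set.seed(3)
  ped <- pedigree(paste0("a", 1:30),
                  c(rep("0", 20), rep("a1", 10)),
                  c(rep("0", 20), paste0("a", 2:11)))
  cfg <- sim_config(missing_rate = 0, seed = 3)
  m <- 200
  base <- hwe_genotypes(30, m, p = runif(m, 0.3, 0.5))
  base$animal_ids <- ped$id
  rownames(base$dos) <- ped$id
  # make offspring rows consistent with parents to avoid natural conflicts
  for (i in 21:30) {
    s <- match(ped$id[ped$sire[i]], base$animal_ids)
    d <- match(ped$id[ped$dam[i]], base$animal_ids)
    base$dos[i, ] <- rbinom(m, 1, base$dos[s, ] / 2) +
      rbinom(m, 1, base$dos[d, ] / 2)
  }
  deg <- degrade(base, ped, cfg, n_monomorphic = 2L, n_hwe = 1L,
                 n_low_call = 3L, n_conflict_animals = 1L,
                 conflict_rate = 0.3)
  planted <- attr(deg, "planted")
  qc <- suppressMessages(run_qc(deg, ped, run_config(seed = 3)))
  rep_ <- qc$report
  removed <- attr(rep_, "removed")
  expect_equal(sort(removed[[1]]), sort(planted$low_call))
  expect_equal(removed[[2]], planted$conflict_animals)
  expect_equal(sort(removed[[3]]), sort(planted$monomorphic))
  expect_equal(sort(removed[[4]]), sort(planted$hwe))
  expect_equal(rep_$criterion,
               c("call_rate", "mendel_conflicts", "maf", "hwe", "ld_prune"))
  expect_false(anyNA(qc$genotypes$dos))
})
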