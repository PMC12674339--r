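write_lines_tmp <- function(lines, ext = ".csv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

test_that("read_pedigree handles order, unknown codes and duplicate ids", {
  f <- write_lines_tmp(c("animal,sire,dam",
                         "kid,pa,ma",
                         "pa,0,",
                         "ma,NA,0"))
  ped <- read_pedigree(f)
  expect_equal(ped$n, 3L)
  kid <- match("kid", ped$id)
  expect_true(all(c(ped$sire[kid], ped$dam[kid]) < kid))

  f2 <- write_lines_tmp(c("animal,sire,dam", "A,0,0", "A,0,0"))
  expect_error(read_pedigree(f2), "A")

  f3 <- write_lines_tmp(c("id,father,mother", "x,0,0"))
  expect_error(read_pedigree(f3), "lacks column")
  expect_equal(read_pedigree(f3, c("id", "father", "mother"))$n, 1L)
})

make_test_vcf <- function() {
  samples <- paste0("s", 1:5)
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=1>", "##contig=<ID=scaffold_12>", "##contig=<ID=MT>",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  row <- function(chrom, pos, id, alt, gts)
    paste(c(chrom, pos, id, "A", alt, ".", "PASS", ".", "GT", gts),
          collapse = "\t")
  body <- c(
    row(1, 100, "v1", "G", c("0/0", "0/1", "1/1", "0/0", "0/1")),
    row(1, 200, "v2", "G", c("./.", "0|1", "1|1", "0/0", "0/0")),
    row(1, 300, "v3", "G,T", c("0/0", "0/1", "2/2", "0/0", "0/0")),  # multi-allelic
    row("scaffold_12", 50, "v4", "G", rep("0/0", 5)),
    row("MT", 10, "v5", "G", rep("0/1", 5)),
    row(2, 150, "v6", "C", c("1/1", "1/1", "0/1", "./.", "0/0")))
  write_lines_tmp(c(hdr, body), ".vcf")
}

test_that("VCF reader matches a hand-built dosage matrix and drops junk contigs", {
  f <- make_test_vcf()
  msgs <- capture_messages(g <- read_genotypes_vcf(f))
  expect_match(paste(msgs, collapse = " "), "multi-allelic")
  expect_equal(n_snps(g), 3L)                    # v1, v2, v6
  expect_equal(g$map$id, c("v1", "v2", "v6"))
  expect_equal(attr(g, "n_multiallelic_skipped"), 1L)
  hand <- rbind(v1 = c(0, 1, 2, 0, 1),
                v2 = c(NA, 1, 2, 0, 0),
                v6 = c(2, 2, 1, NA, 0))
  expect_equal(unname(g$dos), unname(t(hand)))
  expect_equal(g$map$pos, c(100, 200, 150))
  expect_equal(g$animal_ids, paste0("s", 1:5))
})

test_that("VCF round trip through write_vcf preserves dosages and map", {
  set.seed(31)
  g <- hwe_genotypes(6, 12, chrom = rep(c(1, 2), each = 6))
  g$dos[1, 3] <- NA
  f <- tempfile(fileext = ".vcf")
  write_vcf(g, f)
  g2 <- read_genotypes_vcf(f)
  expect_equal(unname(g2$dos), unname(g$dos))
  expect_equal(g2$map$chrom, g$map$chrom)
  expect_equal(g2$map$pos, g$map$pos)
})

test_that("read_phenotypes drops incomplete rows and validates animals", {
  ped <- pedigree(paste0("a", 1:5), rep("0", 5), rep("0", 5))
  f <- write_lines_tmp(c("animal,my,season,age",
                         "a1,100,1,30", "a2,110,2,31", "a3,,1,29",
                         "a4,120,2,28", "a5,130,1,33"))
  ph <- suppressMessages(read_phenotypes(f, "my", "season", "age", ped))
  expect_equal(nrow(ph), 4L)
  expect_equal(attr(ph, "n_dropped"), 1L)
  expect_equal(attr(ph, "trait"), "my")

  f2 <- write_lines_tmp(c("animal,my", "ghost,5"))
  expect_error(suppressMessages(read_phenotypes(f2, "my", ped = ped)), "ghost")
  expect_error(read_phenotypes(f, "missing_trait", ped = ped), "lacks column")
})

test_that("write_results round-trips effects and writes region/empty tables", {
  set.seed(32)
  g <- hwe_genotypes(20, 60)
  p <- allele_frequencies(g)
  Z <- center_matrix(g, p)
  u <- rnorm(60, sd = 0.1)
  w <- window_variances(u, Z, g$map, 30, sigma2_a = 1)
  w$pct_var <- c(0.7, 0.2)
  vc <- structure(list(sigma2_u = 1, sigma2_e = 2, h2 = 1 / 3, se_h2 = 0.1,
                       n_iter = 5L, loglik = -10, converged = TRUE),
                  class = "wss_varcomp")
  out <- tempfile()
  paths <- write_results(u, rep(1, 60), g$map, w, select_regions(w, 0.5),
                         vc, out)
  eff <- read.delim(paths[["snp_effects"]])
  expect_equal(eff$u_hat, unname(u), tolerance = 1e-12)
  expect_equal(eff$snp, g$map$id)
  reg <- read.delim(paths[["regions"]])
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$pct_var, 0.7)

  empty <- w[integer(0), ]
  paths2 <- write_results(u, rep(1, 60), g$map, w,
                          select_regions(empty, 0.5), vc, out)
  expect_equal(nrow(read.delim(paths2[["regions"]])), 0L)
})

test_that("config round-trips through JSON and rejects unknown keys", {
  cfg <- run_config(alpha_blend = 0.8, window_size = 10, seed = 99)
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg[setdiff(names(cfg), "ld_window")], f,
                       auto_unbox = TRUE)
  cfg2 <- read_config(f)
  expect_equal(cfg2$alpha_blend, 0.8)
  expect_equal(cfg2$window_size, 10L)
  expect_equal(cfg2$ld_window, 50L)  # default retained
  jsonlite::write_json(list(bogus = 1), f, auto_unbox = TRUE)
  expect_error(read_config(f), "bogus")
  expect_error(run_config(maf_min = 1.5), "maf_min")
})

test_that("CLI simulate subcommand writes the four artefacts", {
  cfgf <- tempfile(fileext = ".json")
  outd <- file.path(tempdir(), "cli_sim")
  jsonlite::write_json(list(n_founders = 30, n_generations = 2,
                            n_chromosomes = 1, snps_per_chromosome = 30,
                            n_burnin_generations = 5, seed = 5),
                       cfgf, auto_unbox = TRUE)
  suppressMessages(wssgwas_cli(c("simulate", "--config", cfgf,
                                 "--out", outd)))
  expect_true(all(file.exists(file.path(
    outd, c("pedigree.tsv", "genotypes.vcf", "phenotypes.tsv",
            "truth_tbv.tsv")))))
  ped <- read_pedigree(file.path(outd, "pedigree.tsv"))
  expect_equal(ped$n, 60L)
  g <- read_genotypes_vcf(file.path(outd, "genotypes.vcf"))
  expect_equal(n_snps(g), 30L)
})
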