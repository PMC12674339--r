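test_that("back-solving is zero at a_hat = 0 and inverts Z u on full-rank G", {
  set.seed(16)
  n <- 20
  m <- 200
  p_true <- runif(m, 0.2, 0.8)
  g <- hwe_genotypes(n, m, p = p_true)
  Z <- center_matrix(g, p_true)  # external frequencies: G full rank
  G <- g_matrix(Z, NULL, p_true)
  expect_equal(unname(backsolve_snp_effects(rep(0, n), Z, NULL, G, p_true)),
               rep(0, m))
  a_hat <- rnorm(n)
  u <- backsolve_snp_effects(a_hat, Z, NULL, G, p_true)
  expect_equal(drop(Z %*% u), a_hat, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("weight updates normalize u^2*2pq to sum t, with degenerate fallback", {
  # two SNPs, equal p, effects (2, 1): ratio 4:1 -> weights (1.6, 0.4)
  expect_equal(update_weights(c(2, 1), c(0.3, 0.3)), c(1.6, 0.4))
  expect_equal(update_weights(rep(1.3, 5), rep(0.25, 5)), rep(1, 5))
  expect_equal(update_weights(rep(0, 4), rep(0.25, 4), current = rep(2, 4)),
               rep(2, 4))
  w <- update_weights(rnorm(50), runif(50, 0.05, 0.5))
  expect_equal(sum(w), 50)
  expect_true(all(w > 0))
})

test_that("window partitioning and variance bookkeeping are exact", {
  set.seed(17)
  g <- hwe_genotypes(40, 90)
  p <- allele_frequencies(g)
  Z <- center_matrix(g, p)
  u <- rnorm(90, sd = 0.1)
  # one window spanning everything scores exactly 100% of its own variance
  w_all <- window_variances(u, Z, g$map, 90, sigma2_a = var(drop(Z %*% u)))
  expect_equal(nrow(w_all), 1L)
  expect_equal(w_all$pct_var, 100)

  w30 <- window_variances(u, Z, g$map, 30, sigma2_a = 1)
  expect_equal(nrow(w30), 3L)
  expect_equal(w30$n_snps, rep(30L, 3))
  expect_true(all(w30$start_bp[-1] > w30$end_bp[-3]))  # disjoint, ordered

  u0 <- u
  u0[1:30] <- 0
  expect_equal(window_variances(u0, Z, g$map, 30, 1)$pct_var[1], 0)
  expect_error(window_variances(u, Z, g$map, 30, 0), "positive")
})

test_that("trailing short windows are kept and flagged by n_snps", {
  set.seed(18)
  g <- hwe_genotypes(25, 70, chrom = rep(c(1, 2), c(40, 30)))
  u <- rnorm(70, sd = 0.05)
  w <- window_variances(u, Z <- center_matrix(g, allele_frequencies(g)),
                        g$map, 30, 1)
  expect_equal(w$n_snps, c(30L, 10L, 30L))
  expect_equal(w$chrom, c("1", "1", "2"))
})

test_that("window percentages are invariant to allele-coding flips", {
  set.seed(19)
  g <- hwe_genotypes(30, 60)
  p <- allele_frequencies(g)
  Z <- center_matrix(g, p)
  flip <- sample(60, 20)
  g2 <- g
  g2$dos[, flip] <- 2 - g2$dos[, flip]
  p2 <- allele_frequencies(g2)
  Z2 <- center_matrix(g2, p2)
  a_hat <- rnorm(30)
  A22 <- diag(30)
  Gs <- blend_g(g_matrix(Z, NULL, p), A22, 0.95)
  Gs2 <- blend_g(g_matrix(Z2, NULL, p2), A22, 0.95)
  expect_equal(Gs, Gs2, tolerance = 1e-10)
  u1 <- backsolve_snp_effects(a_hat, Z, NULL, Gs, p)
  u2 <- backsolve_snp_effects(a_hat, Z2, NULL, Gs2, p2)
  expect_equal(unname(u2[flip]), unname(-u1[flip]), tolerance = 1e-8)
  w1 <- window_variances(u1, Z, g$map, 30, 1)
  w2 <- window_variances(u2, Z2, g2$map, 30, 1)
  expect_equal(w1$pct_var, w2$pct_var, tolerance = 1e-8)
})

test_that("between-window covariances are small for unlinked SNPs", {
  set.seed(20)
  g <- hwe_genotypes(200, 3000)
  p <- allele_frequencies(g)
  Z <- center_matrix(g, p)
  u <- rnorm(3000, sd = 0.02)
  w <- window_variances(u, Z, g$map, 30, sigma2_a = 1)
  total <- var(drop(Z %*% u))
  expect_lt(abs(sum(w$pct_var) / 100 - total) / total, 0.10)
})

test_that("select_regions uses a strict threshold and descending order", {
  w <- data.frame(window_id = 1:4, chrom = "1", start_bp = 1:4, end_bp = 1:4,
                  first_snp = "a", last_snp = "b", n_snps = 30L,
                  pct_var = c(0.7, 0.4, 2.0, 0.5))
  sel <- select_regions(w, 0.5)
  expect_equal(sel$pct_var, c(2.0, 0.7))   # 0.5 itself excluded
  expect_equal(nrow(select_regions(w[w$pct_var == 0, ], 0.5)), 0L)
})

test_that("manhattan_table offsets chromosomes cumulatively", {
  w <- data.frame(window_id = 1:3, chrom = c("1", "1", "2"),
                  start_bp = c(0, 100, 0), end_bp = c(100, 200, 100),
                  first_snp = "a", last_snp = "b", n_snps = 30L,
                  pct_var = c(1, 2, 3))
  mt <- manhattan_table(w)
  expect_equal(nrow(mt), 3L)
  expect_equal(mt$cum_pos[1:2], mt$pos_bp[1:2])       # first chromosome unshifted
  expect_equal(mt$cum_pos[3], mt$pos_bp[3] + 200)     # offset by chr1 length
})

test_that("one weighting iteration with D = I reproduces the unweighted chain", {
  set.seed(21)
  cfg <- sim_config(n_founders = 60, n_generations = 3, n_chromosomes = 2,
                    snps_per_chromosome = 60, n_qtl = 1, h2 = 0.4,
                    prop_genotyped = 0.3, n_burnin_generations = 5, seed = 21)
  sim <- simulate_dataset(cfg)
  g <- sim$genotypes
  p <- allele_frequencies(g)
  Z <- center_matrix(g, p)
  gi <- match(g$animal_ids, sim$ped$id)
  A22 <- a_submatrix(sim$ped, gi)
  Ainv <- a_inverse(sim$ped)
  des <- build_design(sim$phenotypes, sim$ped)
  vc <- list(sigma2_u = 1, sigma2_e = 1.5)
  rc <- run_config(n_weight_iterations = 1, seed = 21)
  gw <- run_weighted_iterations(des$y, des$X, des$zmap, Z, p, g$map,
                                Ainv, A22, gi, vc, rc)
  expect_length(gw, 1L)
  # manual unweighted chain
  G <- g_matrix(Z, NULL, p)
  Gs <- blend_g(G, A22, rc$alpha_blend)
  Hinv <- h_inverse(Ainv, A22, Gs, gi, rc$alpha_blend)
  fit <- solve_mme(des$y, des$X, des$zmap, Hinv, vc)
  u <- backsolve_snp_effects(fit$a_hat[gi], Z, NULL, Gs, p)
  expect_equal(gw[[1]]$effects, u, tolerance = 1e-10)
  expect_equal(gw[[1]]$weights, rep(1, ncol(Z)))
})

test_that("a null trait produces no runaway weighting between iterations", {
  set.seed(22)
  cfg <- sim_config(n_founders = 80, n_generations = 3, n_chromosomes = 3,
                    snps_per_chromosome = 150, n_qtl = 0, h2 = 0.2,
                    prop_genotyped = 0.35, n_burnin_generations = 10, seed = 22)
  sim <- simulate_dataset(cfg)
  g <- sim$genotypes
  p <- allele_frequencies(g)
  Z <- center_matrix(g, p)
  gi <- match(g$animal_ids, sim$ped$id)
  des <- build_design(sim$phenotypes, sim$ped)
  gw <- run_weighted_iterations(des$y, des$X, des$zmap, Z, p, g$map,
                                a_inverse(sim$ped), a_submatrix(sim$ped, gi),
                                gi, list(sigma2_u = 1, sigma2_e = 4),
                                run_config(seed = 22))
  # one re-weighting round inflates the top noise window by ~3-6x (the
  # weights are the squared effects, so some sharpening is inherent); the
  # sanity check is against extreme runaway, not against that sharpening
  m1 <- max(gw[[1]]$windows$pct_var)
  m2 <- max(gw[[2]]$windows$pct_var)
  expect_lt(m2 / m1, 10)
  expect_lt(m1 / m2, 10)
})
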