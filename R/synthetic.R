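#' Simulation configuration
#'
#' The stated world the simulator emulates: a closed dairy herd recorded over
#' `n_generations` discrete generations (default 8) with a few active sires
#' per generation, of which only a small recent fraction is genotyped; tens
#' of chromosomes of biallelic SNPs at regular map spacing; a handful of
#' large QTL on a polygenic background; seasonal/period fixed effects (9
#' periods x 4 seasons) plus a continuous covariate. Defaults are scaled to
#' desk size (about 1500-2000 animals, 3000 SNPs) so a full analysis runs in
#' seconds to minutes; paper-scale runs just raise the counts.
#'
#' @param n_founders animals per generation (generation size is constant).
#' @param n_generations number of discrete generations including founders.
#' @param offspring_per_mating full sibs per mating pair.
#' @param n_sires number of active sires sampled per generation.
#' @param prop_genotyped fraction of animals genotyped (drawn from the last
#'   three generations).
#' @param n_chromosomes,snps_per_chromosome marker panel shape.
#' @param cm_per_snp inter-SNP map distance in centimorgans (Haldane
#'   recombination). The default 0.1 cM emulates a dense reduced-
#'   representation panel.
#' @param bp_per_snp physical grid spacing in bp.
#' @param ne_ancestral effective size of the ancestral population simulated
#'   before the recorded pedigree starts.
#' @param n_burnin_generations random-mating generations of drift +
#'   recombination in that ancestral population; together with
#'   `ne_ancestral` this sets the baseline linkage disequilibrium
#'   (E\[r^2\] tends to 1/(1 + 4 Ne c)). Set to 0 for founders in exact
#'   linkage equilibrium.
#' @param founder_maf_range range of ancestral ALT allele frequencies.
#' @param n_qtl number of large QTL.
#' @param qtl_variance_fraction fraction of additive genetic variance carried
#'   by the QTL; the rest is spread over a polygenic tail of all other SNPs.
#' @param genetic_variance total additive genetic variance (trait units^2).
#' @param h2 target narrow-sense heritability.
#' @param mu trait mean.
#' @param n_periods,n_seasons numbers of period and season levels.
#' @param period_effect_sd,season_effect_sd SDs of the fixed-effect level
#'   values, trait units.
#' @param covariate_effect slope of the continuous covariate (trait units per
#'   covariate unit).
#' @param missing_rate genotype missingness injected by [degrade()].
#' @param seed integer seed; every simulation draw descends from it.
#' @return List of class `wss_sim_config`.
#' @export
sim_config <- function(n_founders = 190L,
                       n_generations = 8L,
                       offspring_per_mating = 2L,
                       n_sires = 8L,
                       prop_genotyped = 0.1,
                       n_chromosomes = 10L,
                       snps_per_chromosome = 300L,
                       cm_per_snp = 0.1,
                       bp_per_snp = 1e5,
                       ne_ancestral = 40L,
                       n_burnin_generations = 60L,
                       founder_maf_range = c(0.05, 0.5),
                       n_qtl = 1L,
                       qtl_variance_fraction = 0.2,
                       genetic_variance = 1,
                       h2 = 0.3,
                       mu = 10,
                       n_periods = 9L,
                       n_seasons = 4L,
                       period_effect_sd = 0.5,
                       season_effect_sd = 0.25,
                       covariate_effect = 0,
                       missing_rate = 0,
                       seed = 1L) {
  cfg <- as.list(environment())
  for (nm in c("prop_genotyped", "qtl_variance_fraction", "h2",
               "missing_rate"))
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1)
      stop(sprintf("'%s' must be in [0, 1]", nm), call. = FALSE)
  for (nm in c("n_founders", "n_generations", "offspring_per_mating",
               "n_sires", "n_chromosomes", "snps_per_chromosome", "n_qtl",
               "n_periods", "n_seasons", "ne_ancestral",
               "n_burnin_generations"))
    cfg[[nm]] <- as.integer(cfg[[nm]])
  if (length(cfg$founder_maf_range) != 2L ||
      any(cfg$founder_maf_range < 0 | cfg$founder_maf_range > 0.5))
    stop("'founder_maf_range' must be two values in [0, 0.5]", call. = FALSE)
  if (cfg$n_founders < 2L || cfg$n_generations < 1L)
    stop("need at least 2 founders and 1 generation", call. = FALSE)
  class(cfg) <- "wss_sim_config"
  cfg
}

#' Simulate a discrete-generation livestock pedigree
#'
#' Generation 0 holds the founders; each later generation is produced by
#' mating a small random subset of the previous generation's males (the
#' active sires) to its females, `offspring_per_mating` full sibs per pair.
#' Few sires per generation drive up relatedness and pedigree inbreeding, as
#' in real dairy herds. Uses the current RNG state; seed via the caller
#' (e.g. [simulate_dataset()]).
#'
#' @param cfg a [sim_config()].
#' @return A [pedigree()] with attributes `generation` and `sex` per animal.
#' @export
simulate_pedigree <- function(cfg) {
  N <- cfg$n_founders
  id <- paste0("G0_", seq_len(N))
  sire <- dam <- rep(NA_character_, N)
  gen <- rep(0L, N)
  sex <- sample(rep_len(c("M", "F"), N))
  for (g in seq_len(cfg$n_generations - 1L)) {
    prev <- which(gen == g - 1L)
    males <- id[prev][sex[prev] == "M"]
    females <- id[prev][sex[prev] == "F"]
    if (!length(males) || !length(females))
      stop("a generation ran out of one sex; increase n_founders",
           call. = FALSE)
    sires <- sample(males, min(cfg$n_sires, length(males)))
    n_mat <- max(1L, N %/% cfg$offspring_per_mating)
    mat_s <- sample(sires, n_mat, replace = TRUE)
    mat_d <- sample(females, n_mat, replace = TRUE)
    k <- 0L
    for (mtg in seq_len(n_mat)) {
      for (o in seq_len(cfg$offspring_per_mating)) {
        k <- k + 1L
        if (k > N) break
        id <- c(id, sprintf("G%d_%d", g, k))
        sire <- c(sire, mat_s[mtg])
        dam <- c(dam, mat_d[mtg])
        gen <- c(gen, g)
        sex <- c(sex, sample(c("M", "F"), 1L))
      }
    }
  }
  ped <- pedigree(id, sire, dam)
  o <- match(ped$id, id)
  attr(ped, "generation") <- gen[o]
  attr(ped, "sex") <- sex[o]
  ped
}

#' Gene-drop genotypes through a pedigree
#'
#' Ancestral ALT-allele frequencies are drawn uniform over
#' `founder_maf_range` per SNP. A random-mating ancestral population of
#' `ne_ancestral` diploids is then simulated for `n_burnin_generations`
#' generations, letting drift and recombination build distance-decaying
#' linkage disequilibrium (towards E\[r^2\] = 1/(1 + 4 Ne c)), as observed in
#' closed livestock populations; with `n_burnin_generations = 0` founders
#' are in exact linkage/Hardy-Weinberg equilibrium. Pedigree founders draw
#' gametes from the last ancestral generation, and each descendant inherits
#' one recombinant gamete per parent: within a chromosome, adjacent SNPs
#' switch parental haplotype with the Haldane probability
#' r = 0.5 (1 - exp(-2 d)) for map distance d; chromosomes assort
#' independently. Physical positions sit on a regular bp grid.
#'
#' @param ped a [simulate_pedigree()] (or any topologically ordered pedigree).
#' @param cfg a [sim_config()].
#' @return A [genotype_matrix()] for all pedigree animals, with attribute
#'   `founder_p`, the haplotype-pool allele frequencies the founder gametes
#'   were drawn from.
#' @export
gene_drop <- function(ped, cfg) {
  m_chr <- cfg$snps_per_chromosome
  m <- cfg$n_chromosomes * m_chr
  n <- ped$n
  chrom <- rep(seq_len(cfg$n_chromosomes), each = m_chr)
  pos <- rep(seq_len(m_chr), times = cfg$n_chromosomes) * cfg$bp_per_snp
  p0 <- stats::runif(m, cfg$founder_maf_range[1], cfg$founder_maf_range[2])
  d_morgan <- cfg$cm_per_snp / 100
  r_adj <- 0.5 * (1 - exp(-2 * d_morgan))
  # switch probability per adjacent SNP; 0.5 at chromosome starts resets the
  # gamete at every chromosome (independent assortment); position 1 is a
  # uniform start, also 0.5
  rvec <- rep(r_adj, m)
  rvec[match(unique(chrom), chrom)] <- 0.5
  gamete <- function(h1, h2) {
    sw <- stats::runif(m) < rvec
    use2 <- cumsum(sw) %% 2L == 1L
    ifelse(use2, h2, h1)
  }

  # ancestral burn-in: 2*Ne haplotypes under random mating
  ne <- max(2L, cfg$ne_ancestral)
  pool <- t(matrix(as.integer(stats::runif(2L * ne * m) < rep(p0, 2L * ne)),
                   m, 2L * ne))
  for (t_ in seq_len(cfg$n_burnin_generations)) {
    nxt <- matrix(0L, 2L * ne, m)
    for (k in seq_len(2L * ne)) {
      par <- sample.int(ne, 1L)
      nxt[k, ] <- gamete(pool[2L * par - 1L, ], pool[2L * par, ])
    }
    pool <- nxt
  }
  p_pool <- colMeans(pool)

  H1 <- matrix(0L, n, m)
  H2 <- matrix(0L, n, m)
  founder_gamete <- function() {
    par <- sample.int(ne, 1L)
    gamete(pool[2L * par - 1L, ], pool[2L * par, ])
  }
  for (i in seq_len(n)) {
    s <- ped$sire[i]
    d <- ped$dam[i]
    H1[i, ] <- if (is.na(s)) founder_gamete() else gamete(H1[s, ], H2[s, ])
    H2[i, ] <- if (is.na(d)) founder_gamete() else gamete(H1[d, ], H2[d, ])
  }
  g <- genotype_matrix(H1 + H2, chrom, pos,
                       snp_id = sprintf("snp%d_%d", chrom, pos),
                       animal_ids = ped$id)
  attr(g, "founder_p") <- p_pool
  g
}

#' Assign QTL and polygenic effects; compute true breeding values
#'
#' Draws `n_qtl` QTL SNPs at random with Normal effects, spreads the
#' remaining variance over a polygenic tail of all other SNPs, and rescales
#' so the QTL carry `qtl_variance_fraction` of the additive variance and the
#' total variance of the true breeding values equals `genetic_variance`
#' exactly (to floating point).
#'
#' @param g all-animal [genotype_matrix()] from [gene_drop()].
#' @param cfg a [sim_config()].
#' @param focal_animals optional animal ids (e.g. the recent, genotyping-
#'   eligible generations) over which candidate QTL must have minor allele
#'   frequency >= 0.1; a variance-fraction statement is only meaningful for
#'   loci still segregating in the study animals. Default: all animals, with
#'   a 0.05 MAF floor.
#' @return Object of class `wss_truth`: `tbv` (named, centered), `effects`
#'   (all SNPs), `qtl_idx`, `qtl_effects`, `genetic_variance`,
#'   `qtl_variance_fraction` (realized).
#' @export
assign_qtl <- function(g, cfg, focal_animals = NULL) {
  M <- g$dos
  m <- ncol(M)
  if (cfg$n_qtl > m) stop("more QTL than SNPs", call. = FALSE)
  V <- cfg$genetic_variance
  f <- if (cfg$n_qtl == 0L) 0 else cfg$qtl_variance_fraction
  eff <- numeric(m)
  # QTL must segregate in the study animals
  if (is.null(focal_animals)) {
    pobs <- colMeans(M) / 2
    maf_floor <- 0.05
  } else {
    rows <- match(focal_animals, g$animal_ids)
    if (anyNA(rows)) stop("focal animal(s) not genotyped", call. = FALSE)
    pobs <- colMeans(M[rows, , drop = FALSE]) / 2
    maf_floor <- 0.1
  }
  mafok <- which(pmin(pobs, 1 - pobs) >= maf_floor)
  if (cfg$n_qtl > 0L && length(mafok) < cfg$n_qtl)
    stop("not enough polymorphic SNPs to place QTL", call. = FALSE)
  qtl <- if (cfg$n_qtl > 0L) sort(sample(mafok, cfg$n_qtl)) else integer(0)
  poly <- setdiff(seq_len(m), qtl)
  gq <- numeric(nrow(M))
  if (length(qtl)) {
    eq <- stats::rnorm(length(qtl))
    gq <- drop(M[, qtl, drop = FALSE] %*% eq)
    vq <- stats::var(gq)
    sq <- if (vq > 0 && f > 0) sqrt(f * V / vq) else 0
    eff[qtl] <- eq * sq
  }
  gp <- numeric(nrow(M))
  if (length(poly) && f < 1) {
    ep <- stats::rnorm(length(poly), sd = 0.1)
    gp <- drop(M[, poly, drop = FALSE] %*% ep)
    vp <- stats::var(gp)
    sp <- if (vp > 0) sqrt((1 - f) * V / vp) else 0
    eff[poly] <- ep * sp
  }
  tbv <- drop(M %*% eff)
  vt <- stats::var(tbv)
  if (vt > 0) {
    s <- sqrt(V / vt)
    eff <- eff * s
    tbv <- tbv * s
  }
  tbv <- tbv - mean(tbv)
  names(tbv) <- g$animal_ids
  qvf <- if (length(qtl)) {
    gq2 <- drop(g$dos[, qtl, drop = FALSE] %*% eff[qtl])
    stats::var(gq2) / stats::var(drop(g$dos %*% eff))
  } else 0
  structure(list(tbv = tbv, effects = eff, qtl_idx = qtl,
                 qtl_effects = eff[qtl], genetic_variance = V,
                 qtl_variance_fraction = qvf),
            class = "wss_truth")
}

#' Simulate phenotypes with fixed effects
#'
#' y = mu + period + season + beta * covariate + TBV + e, with period
#' assigned from birth generation (cycled over `n_periods`), season uniform,
#' covariate ~ N(30, 5), and residual variance sigma2_e =
#' V (1 - h2) / h2 so that the realized heritability parameter equals
#' `cfg$h2` by construction. `h2 = 1` (zero residual) is allowed for
#' pipeline identities and flagged with a message.
#'
#' @param truth a [assign_qtl()] result.
#' @param ped the pedigree the TBVs belong to.
#' @param cfg a [sim_config()].
#' @return A [phenotype_table()] covering every animal, with attribute
#'   `sigma2_e`.
#' @export
simulate_phenotypes <- function(truth, ped, cfg) {
  n <- ped$n
  V <- stats::var(truth$tbv)
  s2e <- if (cfg$h2 == 0) stop("h2 = 0 leaves no genetic signal to simulate",
                               call. = FALSE)
         else V * (1 - cfg$h2) / cfg$h2
  if (s2e == 0) message("h2 = 1: simulating noise-free phenotypes")
  gen <- attr(ped, "generation")
  if (is.null(gen)) gen <- rep(0L, n)
  period <- (gen %% cfg$n_periods) + 1L
  season <- sample.int(cfg$n_seasons, n, replace = TRUE)
  pe <- stats::rnorm(cfg$n_periods, 0, cfg$period_effect_sd)
  se <- stats::rnorm(cfg$n_seasons, 0, cfg$season_effect_sd)
  cov <- stats::rnorm(n, 30, 5)
  e <- if (s2e > 0) stats::rnorm(n, 0, sqrt(s2e)) else numeric(n)
  y <- cfg$mu + pe[period] + se[season] + cfg$covariate_effect * cov +
    truth$tbv[ped$id] + e
  ph <- phenotype_table(ped$id, y,
                        factors = list(period = period, season = season),
                        covariates = list(afc = cov),
                        trait = "simulated")
  attr(ph, "sigma2_e") <- s2e
  ph
}

#' Degrade a clean genotype matrix for QC testing
#'
#' Plants exactly known violations so every QC filter's removal set is
#' predictable: masks calls at `cfg$missing_rate`, plants monomorphic SNPs
#' (MAF filter), SNPs with only opposing homozygotes (HWE filter), SNPs with
#' most calls missing (call-rate filter), and animals with opposing-homozygote
#' conflicts against a genotyped parent (Mendelian filter).
#'
#' @param g a [genotype_matrix()] (typically the genotyped subset).
#' @param ped pedigree; required when planting conflict animals.
#' @param cfg a [sim_config()] (supplies `missing_rate`).
#' @param n_monomorphic,n_hwe,n_low_call numbers of SNPs to corrupt.
#' @param n_conflict_animals animals to corrupt with parent-progeny
#'   conflicts; each needs a genotyped parent in `g`.
#' @param conflict_rate fraction of parent-homozygous SNPs flipped to the
#'   opposing homozygote in a conflict animal.
#' @param low_call_frac fraction of calls masked in a low-call-rate SNP.
#' @return The degraded matrix with attribute `planted`: list of
#'   `monomorphic`, `hwe`, `low_call` (SNP ids) and `conflict_animals`.
#' @export
degrade <- function(g, ped = NULL, cfg, n_monomorphic = 0L, n_hwe = 0L,
                    n_low_call = 0L, n_conflict_animals = 0L,
                    conflict_rate = 0.05, low_call_frac = 0.5) {
  m <- n_snps(g)
  n <- n_animals(g)
  need <- n_monomorphic + n_hwe + n_low_call
  if (need > m) stop("more planted SNPs than available", call. = FALSE)
  picks <- if (need > 0L) sample.int(m, need) else integer(0)
  take <- function(k) {
    out <- picks[seq_len(k)]
    picks <<- picks[-seq_len(k)]
    out
  }
  mono <- take(n_monomorphic)
  hwe <- take(n_hwe)
  low <- take(n_low_call)
  for (j in mono) g$dos[, j] <- 0
  for (j in hwe) g$dos[, j] <- sample(c(0, 2), n, replace = TRUE)
  for (j in low) {
    k <- ceiling(low_call_frac * n)
    g$dos[sample.int(n, k), j] <- NA
  }
  conflict_ids <- character(0)
  if (n_conflict_animals > 0L) {
    if (is.null(ped)) stop("ped required to plant conflicts", call. = FALSE)
    idx <- match(g$animal_ids, ped$id)
    has_par <- vapply(seq_len(n), function(r) {
      pp <- c(ped$sire[idx[r]], ped$dam[idx[r]])
      pp <- pp[!is.na(pp)]
      length(pp) > 0L && any(ped$id[pp] %in% g$animal_ids)
    }, logical(1))
    cand <- which(has_par)
    if (length(cand) < n_conflict_animals)
      stop("not enough genotyped parent-offspring pairs to plant conflicts",
           call. = FALSE)
    rows <- sample(cand, n_conflict_animals)
    for (r in rows) {
      pp <- c(ped$sire[idx[r]], ped$dam[idx[r]])
      pp <- pp[!is.na(pp)]
      pr <- match(ped$id[pp], g$animal_ids)
      pr <- pr[!is.na(pr)][1L]
      hom <- which(!is.na(g$dos[pr, ]) & g$dos[pr, ] %in% c(0, 2) &
                     !(seq_len(m) %in% c(mono, hwe, low)))
      k <- max(1L, ceiling(conflict_rate * length(hom)))
      flip <- sample(hom, min(k, length(hom)))
      g$dos[r, flip] <- 2 - g$dos[pr, flip]
      conflict_ids <- c(conflict_ids, g$animal_ids[r])
    }
  }
  if (cfg$missing_rate > 0) {
    shield <- c(mono, hwe, low)
    mask <- matrix(stats::runif(n * m) < cfg$missing_rate, n, m)
    if (length(shield)) mask[, shield] <- FALSE
    g$dos[mask] <- NA
  }
  attr(g, "planted") <- list(
    monomorphic = g$map$id[mono], hwe = g$map$id[hwe],
    low_call = g$map$id[low], conflict_animals = conflict_ids)
  g
}

#' Simulate a complete WssGWAS-ready dataset
#'
#' Seeds the RNG once from `cfg$seed`, then chains pedigree simulation, gene
#' dropping, QTL assignment, phenotype simulation and genotyped-subset
#' selection. Genotyped animals are drawn preferentially from recorded dams
#' of the last three generations (recorded breeding females are the animals
#' genotyped in practice), topped up with other recent animals if needed.
#'
#' @param cfg a [sim_config()].
#' @return List with `ped`, `genotypes_all` (every animal),
#'   `genotypes` (genotyped subset), `genotyped_ids`, `truth`, `phenotypes`,
#'   `config`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  ped <- simulate_pedigree(cfg)
  g_all <- gene_drop(ped, cfg)
  gen <- attr(ped, "generation")
  recent <- which(gen >= max(gen) - 2L)
  is_dam <- seq_len(ped$n) %in% ped$dam[!is.na(ped$dam)]
  dams <- recent[is_dam[recent]]
  truth <- assign_qtl(g_all, cfg, focal_animals = ped$id[recent])
  ph <- simulate_phenotypes(truth, ped, cfg)
  n_g <- max(2L, round(cfg$prop_genotyped * ped$n))
  sel <- if (length(dams) >= n_g) sample(dams, n_g)
         else c(dams, sample(setdiff(recent, dams),
                             min(n_g, length(recent)) - length(dams)))
  sel <- sort(sel)
  g <- g_all
  g$dos <- g$dos[sel, , drop = FALSE]
  g$animal_ids <- g$animal_ids[sel]
  list(ped = ped, genotypes_all = g_all, genotypes = g,
       genotyped_ids = g$animal_ids, truth = truth, phenotypes = ph,
       config = cfg)
}
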