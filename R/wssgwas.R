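#' Back-solve SNP effects from genomic breeding values
#'
#' Under the equivalence a = Z u of breeding values and marker effects,
#' u_hat = lambda D Z' (G*)^-1 a_hat with lambda = 1/(2 sum(p q)): the BLUP of
#' marker effects given the genotyped animals' GEBVs. With alpha = 1 and a
#' full-rank G, Z u_hat reproduces a_hat exactly.
#'
#' @param a_hat GEBVs of the genotyped animals, in the row order of `Z`.
#' @param Z centered marker matrix.
#' @param weights diagonal of D (per-SNP variances); default uniform.
#' @param Gstar the (blended) genomic relationship matrix used in the
#'   evaluation, built from the same `Z` and `weights`.
#' @param p per-SNP ALT frequencies defining lambda.
#' @return Named numeric vector of SNP allele-substitution effects.
#' @export
backsolve_snp_effects <- function(a_hat, Z, weights = NULL, Gstar, p) {
  t <- ncol(Z)
  if (is.null(weights)) weights <- uniform_weights(t)
  check_weights(weights, t)
  if (length(a_hat) != nrow(Z) || !all(dim(Gstar) == nrow(Z)))
    stop("a_hat, Z and Gstar dimensions disagree", call. = FALSE)
  lambda <- 1 / (2 * sum(p * (1 - p)))
  u <- lambda * weights * drop(crossprod(Z, solve(Gstar, a_hat)))
  names(u) <- colnames(Z)
  u
}

#' Update marker weights from back-solved SNP effects
#'
#' Raw weight w_j = u_hat_j^2 * 2 p_j q_j (the variance explained by SNP j),
#' normalized so the weights sum to the SNP count: large-effect SNPs gain
#' weight, small-effect SNPs lose it, total scale is preserved. If every raw
#' weight is zero (u_hat = 0) the current weights are returned unchanged.
#'
#' @param u_hat back-solved SNP effects.
#' @param p per-SNP ALT frequencies.
#' @param current weights used in the iteration that produced `u_hat`.
#' @return Normalized positive weight vector, sum = number of SNPs.
#' @export
update_weights <- function(u_hat, p, current = NULL) {
  t <- length(u_hat)
  if (is.null(current)) current <- uniform_weights(t)
  raw <- u_hat^2 * 2 * p * (1 - p)
  if (all(raw == 0)) return(current)
  w <- raw * t / sum(raw)
  # keep strictly positive so D stays invertible
  eps <- 1e-12 * max(w)
  w <- pmax(w, eps)
  w * t / sum(w)
}

#' Per-window percentages of additive genetic variance
#'
#' Splits each chromosome's map-ordered SNPs into consecutive non-overlapping
#' windows of `window_size` (the last window per chromosome may be shorter,
#' flagged by `n_snps`). For window w the local genetic value of each
#' genotyped animal is a_w = Z[, w] u_hat[w]; the window's score is
#' 100 * var(a_w) / sigma2_a, the percent of total additive genetic variance
#' attributed to the window.
#'
#' @param u_hat back-solved SNP effects.
#' @param Z centered marker matrix (genotyped animals x SNPs), columns in map
#'   order.
#' @param map data.frame with chrom, pos, id per SNP (same order as `Z`).
#' @param window_size SNPs per window (default 30).
#' @param sigma2_a total additive genetic variance (REML estimate).
#' @return data.frame of class `wss_windows`: window_id, chrom, start_bp,
#'   end_bp, first_snp, last_snp, n_snps, pct_var.
#' @export
window_variances <- function(u_hat, Z, map, window_size = 30L, sigma2_a) {
  if (sigma2_a <= 0) stop("sigma2_a must be positive", call. = FALSE)
  if (length(u_hat) != ncol(Z) || nrow(map) != ncol(Z))
    stop("u_hat, Z and map dimensions disagree", call. = FALSE)
  rows <- list()
  wid <- 0L
  for (ch in unique(map$chrom)) {
    snps <- which(map$chrom == ch)
    starts <- seq(1L, length(snps), by = window_size)
    for (s in starts) {
      idx <- snps[s:min(s + window_size - 1L, length(snps))]
      wid <- wid + 1L
      a_w <- drop(Z[, idx, drop = FALSE] %*% u_hat[idx])
      rows[[wid]] <- data.frame(
        window_id = wid, chrom = ch,
        start_bp = map$pos[idx[1L]], end_bp = map$pos[idx[length(idx)]],
        first_snp = map$id[idx[1L]], last_snp = map$id[idx[length(idx)]],
        n_snps = length(idx),
        pct_var = 100 * stats::var(a_w) / sigma2_a,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("wss_windows", "data.frame")
  out
}

#' Select candidate genomic regions
#'
#' Windows whose variance percentage strictly exceeds the threshold, ranked
#' in descending order. A window at exactly the threshold is excluded.
#'
#' @param windows a [window_variances()] table.
#' @param threshold_pct percent threshold (default 0.5).
#' @return The selected rows, class `wss_regions`.
#' @export
select_regions <- function(windows, threshold_pct = 0.5) {
  sel <- windows[windows$pct_var > threshold_pct, , drop = FALSE]
  sel <- sel[order(-sel$pct_var), , drop = FALSE]
  rownames(sel) <- NULL
  class(sel) <- c("wss_regions", "data.frame")
  sel
}

#' Manhattan-plot-ready window table
#'
#' One row per window: chromosome, window midpoint in bp, variance percent,
#' and a cumulative genome coordinate obtained by offsetting each chromosome
#' by the running total of preceding chromosome lengths.
#'
#' @param windows a [window_variances()] table.
#' @return data.frame with chrom, pos_bp, pct_var, cum_pos.
#' @export
manhattan_table <- function(windows) {
  chroms <- unique(windows$chrom)
  ends <- vapply(chroms, function(ch)
    max(windows$end_bp[windows$chrom == ch]), numeric(1))
  offset <- stats::setNames(cumsum(c(0, ends[-length(ends)])), chroms)
  mid <- (windows$start_bp + windows$end_bp) / 2
  data.frame(chrom = windows$chrom, pos_bp = mid,
             pct_var = windows$pct_var,
             cum_pos = mid + offset[as.character(windows$chrom)],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Iteratively re-weighted single-step GWAS
#'
#' Runs the weighted ssGWAS loop at fixed variance components: in each
#' iteration G is rebuilt with the current SNP weights, blended with A22,
#' assembled into H^-1, the mixed model is re-solved, SNP effects are
#' back-solved from the genotyped animals' GEBVs, window variances are
#' scored, and the weights are updated for the next round. Iteration 1 with
#' uniform starting weights is the ordinary (unweighted) ssGWAS.
#'
#' @param y,X,zmap model pieces from [build_design()].
#' @param Z centered marker matrix of the genotyped animals.
#' @param p per-SNP ALT frequencies used for G and lambda.
#' @param map SNP map aligned with `Z` columns.
#' @param Ainv sparse pedigree A-inverse.
#' @param A22 pedigree relationship submatrix of the genotyped animals.
#' @param genotyped_index pedigree positions of the genotyped animals, in the
#'   row order of `Z`.
#' @param vc converged `wss_varcomp` (variance components stay frozen).
#' @param config a [run_config()]: supplies alpha_blend, window_size and
#'   n_weight_iterations.
#' @param weights starting weights (default uniform, D = I).
#' @return Object of class `wss_gwas`: list with one element per iteration,
#'   each holding `effects`, `weights` (the D used), `windows`, `fit`; plus
#'   attributes `vc` and `config`.
#' @export
run_weighted_iterations <- function(y, X, zmap, Z, p, map, Ainv, A22,
                                    genotyped_index, vc, config = run_config(),
                                    weights = NULL) {
  t <- ncol(Z)
  D <- if (is.null(weights)) uniform_weights(t) else check_weights(weights, t)
  iters <- vector("list", config$n_weight_iterations)
  for (it in seq_len(config$n_weight_iterations)) {
    res <- tryCatch({
      G <- g_matrix(Z, D, p)
      Gstar <- blend_g(G, A22, config$alpha_blend)
      Hinv <- h_inverse(Ainv, A22, Gstar, genotyped_index,
                        alpha = config$alpha_blend)
      fit <- solve_mme(y, X, zmap, Hinv, vc)
      a_g <- fit$a_hat[genotyped_index]
      u <- backsolve_snp_effects(a_g, Z, D, Gstar, p)
      win <- window_variances(u, Z, map, config$window_size, vc$sigma2_u)
      list(effects = u, weights = D, windows = win, fit = fit)
    }, error = function(e)
      stop(sprintf("weighting iteration %d failed: %s", it,
                   conditionMessage(e)), call. = FALSE))
    iters[[it]] <- res
    D <- update_weights(res$effects, p, D)
  }
  structure(iters, class = "wss_gwas", vc = vc, config = config)
}

#' @export
print.wss_gwas <- function(x, ...) {
  cfg <- attr(x, "config")
  last <- x[[length(x)]]
  sel <- select_regions(last$windows, cfg$region_threshold_pct)
  cat(sprintf(
    "WssGWAS: %d iteration(s), %d SNPs in %d windows; %d region(s) above %.2f%% at iteration %d\n",
    length(x), length(last$effects), nrow(last$windows), nrow(sel),
    cfg$region_threshold_pct, length(x)))
  invisible(x)
}

#' One-call single-step weighted GWAS pipeline
#'
#' Convenience wrapper: genotype QC, pedigree algebra (A22, A-inverse),
#' fixed-effect design, AI-REML variance components under the unweighted
#' (D = I) H matrix, then the weighted iteration loop and region selection.
#'
#' @param ped a [pedigree()].
#' @param genotypes a [genotype_matrix()] (pre-QC).
#' @param phenotypes a prepared [phenotype_table()].
#' @param config a [run_config()].
#' @return List with `qc`, `vc`, `gwas` (per-iteration trajectory),
#'   `windows` (final iteration), `regions`, `effects`, `weights`, `design`.
#' @export
run_wssgwas <- function(ped, genotypes, phenotypes, config = run_config()) {
  qc <- run_qc(genotypes, ped, config)
  g <- qc$genotypes
  p <- qc$freqs
  Z <- center_matrix(g, p)
  genotyped_index <- match(g$animal_ids, ped$id)
  A22 <- a_submatrix(ped, genotyped_index)
  Ainv <- a_inverse(ped)
  des <- build_design(phenotypes, ped)

  G <- g_matrix(Z, NULL, p)
  Gstar <- blend_g(G, A22, config$alpha_blend)
  Hinv <- h_inverse(Ainv, A22, Gstar, genotyped_index, config$alpha_blend)
  vc <- reml_aireml(des$y, des$X, des$zmap, Hinv)

  gwas <- run_weighted_iterations(des$y, des$X, des$zmap, Z, p, g$map,
                                  Ainv, A22, genotyped_index, vc, config)
  last <- gwas[[length(gwas)]]
  list(qc = qc, vc = vc, gwas = gwas, windows = last$windows,
       regions = select_regions(last$windows, config$region_threshold_pct),
       effects = last$effects, weights = last$weights, design = des)
}
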