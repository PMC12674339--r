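# Shared fixtures and independent oracles. Everything is built in code; no
# binary data ships with the package.

# trio: unrelated sire s and dam d with offspring o
trio_ped <- function() pedigree(c("s", "d", "o"), c("0", "0", "s"),
                                c("0", "0", "d"))

# sire x dam -> full sibs a, b -> their offspring x (F_x = 0.25)
fullsib_ped <- function() pedigree(
  c("s", "d", "a", "b", "x"),
  c("0", "0", "s", "s", "a"),
  c("0", "0", "d", "d", "b"))

# random multi-generation pedigree for property tests
random_ped <- function(n_founders = 20, n_extra = 80) {
  id <- paste0("a", seq_len(n_founders + n_extra))
  sire <- dam <- rep(NA_character_, n_founders + n_extra)
  for (i in n_founders + seq_len(n_extra)) {
    pars <- sample(seq_len(i - 1L), 2L)
    sire[i] <- id[pars[1L]]
    dam[i] <- id[pars[2L]]
  }
  pedigree(id, sire, dam)
}

# genotype matrix with explicit dosage columns (list of vectors)
toy_genotypes <- function(cols, chrom = NULL, pos = NULL) {
  d <- do.call(cbind, cols)
  m <- ncol(d)
  if (is.null(chrom)) chrom <- rep(1, m)
  if (is.null(pos)) pos <- seq_len(m) * 1000
  genotype_matrix(d, chrom, pos)
}

# unrelated Hardy-Weinberg genotypes (no pedigree structure, no linkage)
hwe_genotypes <- function(n, m, p = NULL, chrom = NULL) {
  if (is.null(p)) p <- runif(m, 0.1, 0.5)
  d <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  if (is.null(chrom)) chrom <- rep(1, m)
  genotype_matrix(d, chrom, seq_len(m) * 1000)
}

# independent dense REML log-likelihood: direct V-based formula, no
# rotation/eigen tricks shared with the implementation
oracle_reml_ll <- function(y, X, K, s2u, s2e) {
  n <- length(y)
  V <- s2u * K + diag(s2e, n)
  cV <- chol(V)
  Vi <- chol2inv(cV)
  XtViX <- crossprod(X, Vi %*% X)
  P <- Vi - Vi %*% X %*% solve(XtViX, crossprod(X, Vi))
  -0.5 * (2 * sum(log(diag(cV))) + determinant(XtViX)$modulus[1] +
          drop(crossprod(y, P %*% y)) + (n - ncol(X)) * log(2 * pi))
}

# blockwise dense construction of H from A and G* (joint-distribution form)
oracle_dense_H <- function(A, Gstar, gi) {
  n <- nrow(A)
  i1 <- setdiff(seq_len(n), gi)
  A11 <- A[i1, i1, drop = FALSE]
  A12 <- A[i1, gi, drop = FALSE]
  A22 <- A[gi, gi, drop = FALSE]
  A22i <- solve(A22)
  H <- matrix(0, n, n)
  H[i1, i1] <- A11 + A12 %*% A22i %*% (Gstar - A22) %*% A22i %*% t(A12)
  H[i1, gi] <- A12 %*% A22i %*% Gstar
  H[gi, i1] <- t(H[i1, gi])
  H[gi, gi] <- Gstar
  H
}

# find the window row containing a given SNP id
window_of_snp <- function(windows, map, snp_id) {
  j <- match(snp_id, map$id)
  which(windows$chrom == map$chrom[j] &
          windows$start_bp <= map$pos[j] &
          windows$end_bp >= map$pos[j])
}
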