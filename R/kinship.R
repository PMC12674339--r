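#' Uniform marker weights
#'
#' The diagonal of D at the start of a weighted single-step analysis: every
#' SNP contributes equally (D = I).
#'
#' @param t number of SNPs.
#' @return Numeric vector of ones, length `t`.
#' @export
uniform_weights <- function(t) rep(1, t)

check_weights <- function(d, t) {
  if (length(d) != t) stop("weight length must equal SNP count", call. = FALSE)
  if (any(!is.finite(d)) || any(d <= 0))
    stop("marker weights must be finite and positive", call. = FALSE)
  d
}

#' Weighted genomic relationship matrix (VanRaden)
#'
#' G = Z D Z' / (2 * sum(p q)) with Z the allele-frequency-centered dosage
#' matrix and D = diag(weights). With unit weights this is VanRaden's method 1.
#'
#' @param Z centered marker matrix from [center_matrix()].
#' @param weights per-SNP positive weights (diagonal of D); default uniform.
#' @param p per-SNP ALT allele frequencies used for the 2*sum(pq) scale.
#' @return Dense symmetric matrix, genotyped animals x genotyped animals.
#' @export
g_matrix <- function(Z, weights = NULL, p) {
  t <- ncol(Z)
  if (is.null(weights)) weights <- uniform_weights(t)
  check_weights(weights, t)
  if (length(p) != t) stop("frequency length must equal SNP count", call. = FALSE)
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0)
    stop("2*sum(pq) is zero: all SNPs monomorphic; cannot scale G",
         call. = FALSE)
  G <- tcrossprod(Z * rep(weights, each = nrow(Z)), Z) / denom
  (G + t(G)) / 2
}

#' Blend G with the pedigree submatrix A22
#'
#' G* = alpha G + (1 - alpha) A22. Blending with alpha < 1 guarantees an
#' invertible G* even when G itself is singular (as it always is when allele
#' frequencies are estimated from the genotyped sample).
#'
#' @param G genomic relationship matrix.
#' @param A22 pedigree relationship submatrix for the same animals, same order.
#' @param alpha weight on G, in \[0, 1\].
#' @return Dense symmetric matrix.
#' @export
blend_g <- function(G, A22, alpha) {
  if (!all(dim(G) == dim(A22)))
    stop("G and A22 dimensions differ", call. = FALSE)
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]", call. = FALSE)
  alpha * G + (1 - alpha) * A22
}

#' Assemble the single-step H-inverse
#'
#' H^-1 = A^-1 + [0 0; 0 (G*)^-1 - (A22)^-1] on the genotyped block: pedigree
#' relationships everywhere, corrected by genomic information for genotyped
#' animals. With an empty genotyped set (or G* = A22) this is exactly A^-1.
#'
#' @param Ainv sparse A-inverse from [a_inverse()], all pedigree animals.
#' @param A22 dense pedigree relationship submatrix of the genotyped animals.
#' @param Gstar blended genomic relationship matrix, same animals/order.
#' @param genotyped_index positions of the genotyped animals in the pedigree
#'   (rows of `Ainv`), in the row order of `Gstar`.
#' @param alpha blend fraction used to build `Gstar` (recorded only).
#' @return Object of class `wss_hinv`: list with sparse symmetric `matrix`,
#'   `genotyped_index` and `alpha`.
#' @export
h_inverse <- function(Ainv, A22, Gstar, genotyped_index, alpha = NA_real_) {
  n <- nrow(Ainv)
  gi <- as.integer(genotyped_index)
  H <- Matrix::drop0(Ainv * 1)  # dgCMatrix copy
  if (length(gi)) {
    if (!all(dim(Gstar) == c(length(gi), length(gi))) ||
        !all(dim(A22) == dim(Gstar)))
      stop("Gstar/A22 dimensions must match the genotyped set", call. = FALSE)
    if (rcond(Gstar) < 1e-12)
      stop("G* is singular; blend with alpha < 1 (blend_g)", call. = FALSE)
    Gi <- tryCatch(chol2inv(chol(Gstar)), error = function(e)
      stop("G* is singular; blend with alpha < 1 (blend_g)", call. = FALSE))
    A22i <- chol2inv(chol(A22))
    block <- Gi - A22i
    corr <- Matrix::sparseMatrix(
      i = rep(gi, times = length(gi)),
      j = rep(gi, each = length(gi)),
      x = as.numeric(block), dims = c(n, n))
    H <- H + corr
  }
  H <- Matrix::forceSymmetric((H + Matrix::t(H)) / 2)
  structure(list(matrix = H, genotyped_index = gi, alpha = alpha),
            class = "wss_hinv")
}

#' @export
print.wss_hinv <- function(x, ...) {
  cat(sprintf("H-inverse: %d animals, %d genotyped (alpha = %s)\n",
              nrow(x$matrix), length(x$genotyped_index), format(x$alpha)))
  invisible(x)
}

# accept either a wss_hinv or a bare (sparse) precision matrix
hinv_matrix <- function(Hinv) {
  if (inherits(Hinv, "wss_hinv")) Hinv$matrix else Hinv
}
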