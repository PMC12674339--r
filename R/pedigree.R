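#' Construct a pedigree
#'
#' Builds a validated, topologically ordered pedigree from animal/sire/dam
#' identifier vectors. Unknown parents may be coded `NA`, `""`, `"0"` or
#' `"NA"`. Rows are reordered so every parent precedes its offspring; parents
#' that never appear as animals are added as founders.
#'
#' @param animal,sire,dam character (or coercible) identifier vectors of equal
#'   length.
#' @return An object of class `wss_pedigree`: a list with elements `id`
#'   (character labels in topological order), `sire` and `dam` (integer
#'   positions into `id`, `NA` for unknown) and `n`.
#' @export
#' @examples
#' ped <- pedigree(c("s", "d", "x"), c("0", "0", "s"), c("0", "0", "d"))
#' ped$n
pedigree <- function(animal, sire, dam) {
  animal <- as.character(animal)
  sire <- as.character(sire)
  dam <- as.character(dam)
  if (length(sire) != length(animal) || length(dam) != length(animal))
    stop("animal, sire and dam must have equal length", call. = FALSE)
  unk <- function(x) is.na(x) | x %in% c("", "0", "NA")
  sire[unk(sire)] <- NA_character_
  dam[unk(dam)] <- NA_character_

  dup <- unique(animal[duplicated(animal)])
  if (length(dup))
    stop("duplicate animal id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  self <- animal == sire | animal == dam
  if (any(self, na.rm = TRUE))
    stop("animal(s) recorded as own parent: ",
         paste(animal[which(self)], collapse = ", "), call. = FALSE)

  # parents never listed as animals become founders
  extra <- setdiff(stats::na.omit(c(sire, dam)), animal)
  if (length(extra)) {
    animal <- c(extra, animal)
    sire <- c(rep(NA_character_, length(extra)), sire)
    dam <- c(rep(NA_character_, length(extra)), dam)
  }
  n <- length(animal)
  si <- match(sire, animal)
  di <- match(dam, animal)

  # Kahn topological sort; a leftover node means a cycle (animal is its own
  # ancestor)
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    ord <- c(ord, v)
    for (k in kids[[v]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(ord) != n) {
    bad <- setdiff(seq_len(n), ord)
    stop("pedigree cycle: animal(s) ", paste(animal[bad], collapse = ", "),
         " are their own ancestors", call. = FALSE)
  }
  pos <- integer(n)
  pos[ord] <- seq_len(n)
  obj <- list(
    id = animal[ord],
    sire = pos[si][ord],
    dam = pos[di][ord],
    n = n
  )
  class(obj) <- "wss_pedigree"
  obj
}

#' @export
print.wss_pedigree <- function(x, ...) {
  nf <- sum(is.na(x$sire) & is.na(x$dam))
  cat(sprintf("Pedigree: %d animals (%d founders)\n", x$n, nf))
  invisible(x)
}

#' Tabular additive (numerator) relationship matrix
#'
#' Dense recursive construction of Wright's numerator relationship matrix A:
#' A_ii = 1 + 0.5 A(sire, dam), A_ij = 0.5 (A_j,sire + A_j,dam) for j earlier
#' in the topological order, with unknown parents contributing zero. Exact and
#' intended for desk-scale pedigrees (a few thousand animals).
#'
#' @param ped a [pedigree()].
#' @return Dense symmetric numeric matrix with animal ids as dimnames.
#' @export
a_matrix <- function(ped) {
  stopifnot(inherits(ped, "wss_pedigree"))
  n <- ped$n
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- ped$sire[i]
    d <- ped$dam[i]
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
    if (i > 1L) {
      j <- seq_len(i - 1L)
      as_ <- if (!is.na(s)) A[j, s] else 0
      ad_ <- if (!is.na(d)) A[j, d] else 0
      aij <- 0.5 * (as_ + ad_)
      A[j, i] <- aij
      A[i, j] <- aij
    }
  }
  A
}

#' Pedigree inbreeding coefficients
#'
#' F_i = A_ii - 1, with founders (both parents unknown) at 0 and
#' F_i = 0.5 A(sire_i, dam_i) otherwise.
#'
#' @param ped a [pedigree()].
#' @param method `"tabular"` (reference: diagonal of [a_matrix()]) or
#'   `"meuwissen-luo"` (L-column algorithm; identical values, less memory).
#' @return Named numeric vector of per-animal inbreeding coefficients.
#' @export
inbreeding <- function(ped, method = c("tabular", "meuwissen-luo")) {
  method <- match.arg(method)
  if (method == "tabular") {
    F <- diag(a_matrix(ped)) - 1
    names(F) <- ped$id
    return(F)
  }
  meuwissen_luo_f(ped)
}

# Meuwissen & Luo style computation of inbreeding: for each animal, build the
# column of L restricted to its ancestors and accumulate sum(L^2 d).
meuwissen_luo_f <- function(ped) {
  n <- ped$n
  F <- numeric(n)
  dvec <- numeric(n)
  for (i in seq_len(n)) {
    s <- ped$sire[i]
    d <- ped$dam[i]
    Fs <- if (is.na(s)) -1 else F[s]
    Fd <- if (is.na(d)) -1 else F[d]
    dvec[i] <- 0.5 - 0.25 * (Fs + Fd)
    if (is.na(s) || is.na(d)) {
      F[i] <- 0
      next
    }
    L <- numeric(i)
    L[i] <- 1
    aii <- 0
    for (j in i:1) {
      if (L[j] == 0) next
      aii <- aii + L[j]^2 * dvec[j]
      sj <- ped$sire[j]
      dj <- ped$dam[j]
      if (!is.na(sj)) L[sj] <- L[sj] + 0.5 * L[j]
      if (!is.na(dj)) L[dj] <- L[dj] + 0.5 * L[j]
      L[j] <- 0
    }
    # aii here is A_ii of the *parent-average* animal i computed with its own
    # Mendelian term; relationship between sire and dam follows from
    # A_ii = 1 + F_i = sum L^2 d
    F[i] <- aii - 1
  }
  names(F) <- ped$id
  F
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding: each animal contributes 1/d_i at (i,i),
#' -1/(2 d_i) at (i, parent) and 1/(4 d_i) at (parent, parent) and (sire, dam),
#' with Mendelian-sampling variance d_i = 0.5 - 0.25 (F_s + F_d) (both parents
#' known), 0.75 - 0.25 F_known (one known) or 1 (none known).
#'
#' @param ped a [pedigree()].
#' @param F inbreeding coefficients as returned by [inbreeding()]; computed if
#'   missing.
#' @return Sparse symmetric matrix (`Matrix::dsCMatrix`) of dimension n x n.
#' @export
a_inverse <- function(ped, F = NULL) {
  stopifnot(inherits(ped, "wss_pedigree"))
  if (is.null(F)) F <- inbreeding(ped)
  n <- ped$n
  s <- ped$sire
  d <- ped$dam
  Fs <- ifelse(is.na(s), 0, F[ifelse(is.na(s), 1L, s)])
  Fd <- ifelse(is.na(d), 0, F[ifelse(is.na(d), 1L, d)])
  npar <- (!is.na(s)) + (!is.na(d))
  dvec <- ifelse(npar == 2L, 0.5 - 0.25 * (Fs + Fd),
          ifelse(npar == 1L, 0.75 - 0.25 * (Fs + Fd), 1))
  if (any(dvec <= 0))
    stop("non-positive Mendelian sampling variance; inconsistent F",
         call. = FALSE)
  b <- 1 / dvec

  ii <- jj <- integer(0)
  xx <- numeric(0)
  add <- function(i, j, x) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, x)
  }
  add(seq_len(n), seq_len(n), b)
  for (ptype in list(s, d)) {
    k <- which(!is.na(ptype))
    p <- ptype[k]
    add(k, p, -b[k] / 2)
    add(p, k, -b[k] / 2)
    add(p, p, b[k] / 4)
  }
  both <- which(!is.na(s) & !is.na(d))
  add(s[both], d[both], b[both] / 4)
  add(d[both], s[both], b[both] / 4)

  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ped$id, ped$id))
  Matrix::forceSymmetric(Ainv)
}

#' Relationship submatrix for a set of animals
#'
#' Restriction of the full tabular A to the requested animals (typically the
#' genotyped set, i.e. A22). Diagonal entries equal 1 + F_i.
#'
#' @param ped a [pedigree()].
#' @param ids character animal labels, or integer positions in `ped$id`.
#' @return Dense symmetric matrix in the order of `ids`.
#' @export
a_submatrix <- function(ped, ids) {
  stopifnot(inherits(ped, "wss_pedigree"))
  if (is.character(ids)) {
    idx <- match(ids, ped$id)
    if (anyNA(idx))
      stop("animal id(s) not in pedigree: ",
           paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
  } else {
    idx <- as.integer(ids)
    if (any(idx < 1L | idx > ped$n))
      stop("animal position(s) out of range", call. = FALSE)
  }
  a_matrix(ped)[idx, idx, drop = FALSE]
}
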