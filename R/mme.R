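#' Sturges classification of a continuous covariate
#'
#' Discretizes a continuous vector into k = ceiling(1 + 3.322 log10(n))
#' equal-width classes over [min, max], the classical Sturges rule used to
#' group covariates such as age at first calving into factor levels.
#'
#' @param values numeric vector, n >= 1.
#' @return List with `class` (integer class index per value, 1..k), `k` and
#'   `breaks`. A constant vector yields a single class.
#' @export
#' @examples
#' sturges_classes(rnorm(100))$k  # 8
sturges_classes <- function(values) {
  values <- as.numeric(values)
  if (!length(values) || anyNA(values))
    stop("values must be non-empty and free of NAs", call. = FALSE)
  n <- length(values)
  k <- as.integer(ceiling(1 + 3.322 * log10(n)))
  if (k < 1L) k <- 1L
  rng <- range(values)
  if (rng[1] == rng[2] || k == 1L)
    return(list(class = rep(1L, n), k = 1L, breaks = c(rng[1], rng[2])))
  breaks <- seq(rng[1], rng[2], length.out = k + 1L)
  cls <- findInterval(values, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  list(class = as.integer(cls), k = k, breaks = breaks)
}

#' Assemble a phenotype table
#'
#' @param animal animal identifiers (must exist in the pedigree when the
#'   table is used to build a design).
#' @param y trait values.
#' @param factors named list/data.frame of categorical model terms.
#' @param covariates named list/data.frame of continuous model terms.
#' @param trait trait name (bookkeeping only).
#' @return Object of class `wss_phenotypes` (a data.frame with attributes
#'   `trait`, `factors`, `covariates`).
#' @export
phenotype_table <- function(animal, y, factors = list(), covariates = list(),
                            trait = "trait") {
  df <- data.frame(animal = as.character(animal), y = as.numeric(y),
                   stringsAsFactors = FALSE)
  for (nm in names(factors)) df[[nm]] <- factors[[nm]]
  for (nm in names(covariates)) df[[nm]] <- as.numeric(covariates[[nm]])
  structure(df, trait = trait, factors = names(factors),
            covariates = names(covariates),
            class = c("wss_phenotypes", "data.frame"))
}

#' Phenotype preparation: trait floors and outlier pruning
#'
#' Applies trait-specific validity rules (e.g. a 305-day milk yield below
#' 500 kg or a lactation length under 100 days is discarded as a recording
#' artefact), then removes records outside mean +/- `outlier_sd` standard
#' deviations of the remaining data.
#'
#' @param ph a [phenotype_table()].
#' @param outlier_sd SD multiplier for the outlier window (default 3).
#' @param trait_rules optional list with elements `min` and/or `max`: hard
#'   floors/ceilings applied to `y` before outlier pruning.
#' @return The filtered `wss_phenotypes`, with attribute `n_removed` (named:
#'   rule, outlier).
#' @export
prepare_phenotypes <- function(ph, outlier_sd = 3, trait_rules = NULL) {
  stopifnot(inherits(ph, "wss_phenotypes"))
  n0 <- nrow(ph)
  keep <- rep(TRUE, n0)
  if (!is.null(trait_rules$min)) keep <- keep & ph$y >= trait_rules$min
  if (!is.null(trait_rules$max)) keep <- keep & ph$y <= trait_rules$max
  n_rule <- sum(!keep)
  out <- ph[keep, , drop = FALSE]
  mu <- mean(out$y)
  sdv <- stats::sd(out$y)
  keep2 <- if (is.na(sdv) || sdv == 0) rep(TRUE, nrow(out))
           else abs(out$y - mu) <= outlier_sd * sdv
  n_out <- sum(!keep2)
  out <- out[keep2, , drop = FALSE]
  if (nrow(out) < 2L)
    stop("fewer than 2 phenotype records remain after preparation",
         call. = FALSE)
  message(sprintf("phenotypes [%s]: removed %d (rules) + %d (outliers), %d remaining",
                  attr(ph, "trait"), n_rule, n_out, nrow(out)))
  attr(out, "n_removed") <- c(rule = n_rule, outlier = n_out)
  out
}

#' Fixed-effect design and animal incidence map
#'
#' Builds X as intercept + treatment-coded factor columns + covariates, drops
#' rank-deficient columns (logged), and maps each record to its animal's
#' position in the pedigree.
#'
#' @param ph a prepared [phenotype_table()].
#' @param ped a [pedigree()].
#' @return List with `y`, `X` (full column rank), `zmap` (integer pedigree
#'   position per record) and `dropped` (names of removed columns).
#' @export
build_design <- function(ph, ped) {
  stopifnot(inherits(ph, "wss_phenotypes"), inherits(ped, "wss_pedigree"))
  zmap <- match(ph$animal, ped$id)
  if (anyNA(zmap))
    stop("phenotyped animal(s) not in pedigree: ",
         paste(unique(ph$animal[is.na(zmap)]), collapse = ", "),
         call. = FALSE)
  terms <- c(attr(ph, "factors"), attr(ph, "covariates"))
  df <- as.data.frame(ph)
  for (f in attr(ph, "factors")) df[[f]] <- factor(df[[f]])
  fml <- if (length(terms))
    stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  else ~1
  X <- stats::model.matrix(fml, data = df)
  qrX <- qr(X)
  dropped <- character(0)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- colnames(X)[-keep]
    message("build_design: dropped rank-deficient column(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, sort(keep), drop = FALSE]
  }
  if (ncol(X) == 0L) stop("design matrix has rank 0", call. = FALSE)
  list(y = ph$y, X = X, zmap = zmap, dropped = dropped)
}

# Rotate the animal model into the eigenbasis of K = Z_s H Z_s', where H is
# the relationship matrix implied by Hinv and Z_s the record->animal
# incidence. In that basis V = sigma2_u * lambda + sigma2_e is diagonal and
# every REML quantity is O(n p) per evaluation.
reml_rotate <- function(y, X, zmap, Hinv) {
  Hm <- hinv_matrix(Hinv)
  Hd <- as.matrix(Hm)
  H <- chol2inv(chol(Hd))
  K <- H[zmap, zmap, drop = FALSE]
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  list(lam = lam, yt = drop(crossprod(e$vectors, y)),
       Xt = crossprod(e$vectors, X))
}

# REML quantities at theta = c(sigma2_u, sigma2_e) in the rotated basis.
reml_eval <- function(rot, theta) {
  lam <- rot$lam; yt <- rot$yt; Xt <- rot$Xt
  n <- length(yt); p <- ncol(Xt)
  v <- theta[1] * lam + theta[2]
  if (any(v <= 0)) return(NULL)
  W <- Xt / v
  XtVX <- crossprod(Xt, W)
  R <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  B <- chol2inv(R)
  Py <- drop(yt / v - W %*% (B %*% crossprod(Xt, yt / v)))
  yPy <- sum(yt * Py)
  ll <- -0.5 * (sum(log(v)) + 2 * sum(log(diag(R))) + yPy +
                (n - p) * log(2 * pi))
  # tr(P K_i) and y'P K_i P y for K_1 = diag(lam), K_2 = I
  XB <- Xt %*% B
  trP <- function(m) sum(m / v) - sum(XB * (Xt * (m / v^2)))
  Pt <- function(t) drop(t / v - W %*% (B %*% crossprod(Xt, t / v)))
  t1 <- lam * Py; t2 <- Py
  P1 <- Pt(t1); P2 <- Pt(t2)
  score <- -0.5 * c(trP(lam) - sum(lam * Py^2),
                    trP(rep(1, n)) - sum(Py^2))
  AI <- 0.5 * matrix(c(sum(t1 * P1), sum(t1 * P2),
                       sum(t2 * P1), sum(t2 * P2)), 2, 2)
  list(ll = ll, score = score, AI = AI, Py = Py, yPy = yPy,
       yPKPy = c(sum(lam * Py^2), sum(Py^2)),
       trPK = c(trP(lam), trP(rep(1, n))))
}

#' AI-REML variance components for the single-step animal model
#'
#' Estimates additive and residual variances of y = Xb + Z u + e with
#' u ~ N(0, H sigma2_u) and e ~ N(0, I sigma2_e) by restricted maximum
#' likelihood, using average-information (AI) updates with a multiplicative
#' EM-style fallback whenever an AI step would leave the parameter space or
#' reduce the likelihood. The model is rotated once into the eigenbasis of
#' Z H Z', after which every iteration is linear in the record count.
#' Standard errors come from the inverse AI matrix at convergence.
#'
#' @param y,X,zmap response, full-rank fixed design and record->pedigree map
#'   from [build_design()].
#' @param Hinv a [h_inverse()] (or any symmetric positive-definite precision
#'   matrix over pedigree animals, e.g. [a_inverse()] for pedigree-only BLUP,
#'   or an identity for an unrelated-animal model).
#' @param start optional starting values `c(sigma2_u, sigma2_e)`; default
#'   splits var(y) equally.
#' @param max_iter,tol iteration cap and relative-change convergence
#'   tolerance.
#' @return Object of class `wss_varcomp`: sigma2_u, sigma2_e, h2, se_h2,
#'   se_sigma2_u, se_sigma2_e, converged, n_iter, loglik.
#' @export
reml_aireml <- function(y, X, zmap, Hinv, start = NULL, max_iter = 100L,
                        tol = 1e-8) {
  n <- length(y)
  vy <- stats::var(y)
  lb_u <- 1e-8 * vy  # boundary guard: h2 ~ 0 stays estimable
  lb_e <- 1e-10 * vy
  theta <- if (is.null(start)) c(vy / 2, vy / 2) else as.numeric(start)
  rot <- reml_rotate(y, X, zmap, Hinv)
  ev <- reml_eval(rot, theta)
  if (is.null(ev)) stop("REML likelihood undefined at start", call. = FALSE)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    cand <- theta + tryCatch(drop(solve(ev$AI, ev$score)),
                             error = function(e) rep(NA_real_, 2))
    ok <- all(is.finite(cand)) && cand[1] >= lb_u && cand[2] >= lb_e
    ev_new <- if (ok) reml_eval(rot, cand) else NULL
    if (is.null(ev_new) || ev_new$ll < ev$ll - 1e-10) {
      # EM-style fixed-point fallback: theta_i <- theta_i * yPKPy / trPK
      ratio <- ev$yPKPy / pmax(ev$trPK, .Machine$double.eps)
      cand <- pmax(theta * ratio, c(lb_u, lb_e))
      ev_new <- reml_eval(rot, cand)
      if (is.null(ev_new)) break
    }
    delta <- max(abs(cand - theta) / pmax(abs(theta), lb_e))
    theta <- cand
    ev <- ev_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  s2u <- theta[1]
  s2e <- theta[2]
  h2 <- s2u / (s2u + s2e)
  AIinv <- tryCatch(solve(ev$AI), error = function(e)
    matrix(NA_real_, 2, 2))
  gr <- c(s2e, -s2u) / (s2u + s2e)^2
  se_h2 <- sqrt(max(0, drop(t(gr) %*% AIinv %*% gr)))
  structure(list(
    sigma2_u = s2u, sigma2_e = s2e, h2 = h2,
    se_sigma2_u = sqrt(max(0, AIinv[1, 1])),
    se_sigma2_e = sqrt(max(0, AIinv[2, 2])),
    se_h2 = se_h2, converged = converged, n_iter = it, loglik = ev$ll
  ), class = "wss_varcomp")
}

#' @export
print.wss_varcomp <- function(x, ...) {
  cat(sprintf(
    "AI-REML: sigma2_u = %.5g, sigma2_e = %.5g, h2 = %.4f +/- %.4f\n  %s in %d iterations, logL = %.4f\n",
    x$sigma2_u, x$sigma2_e, x$h2, x$se_h2,
    if (x$converged) "converged" else "NOT converged", x$n_iter, x$loglik))
  invisible(x)
}

#' Solve the single-step mixed model equations
#'
#' Solves [X'X  X'Zs; Zs'X  Zs'Zs + Hinv * sigma2_e/sigma2_u] [b; a] =
#' [X'y; Zs'y]. Every pedigree animal gets a breeding value; animals without
#' records are predicted through relationships. In the sigma2_u -> 0 limit
#' breeding values are all zero and b is ordinary least squares.
#'
#' @inheritParams reml_aireml
#' @param vc a `wss_varcomp` (or list with sigma2_u, sigma2_e).
#' @return Object of class `wss_mme_fit`: `b_hat`, `a_hat` (named by animal),
#'   and `residual_rel`, the relative MME residual norm.
#' @export
solve_mme <- function(y, X, zmap, Hinv, vc) {
  if (vc$sigma2_e <= 0) stop("sigma2_e must be positive", call. = FALSE)
  Hm <- hinv_matrix(Hinv)
  n_ped <- nrow(Hm)
  ids <- rownames(Hm)
  if (vc$sigma2_u <= 0) {
    b <- qr.coef(qr(X), y)
    fit <- list(b_hat = b, a_hat = stats::setNames(numeric(n_ped), ids),
                residual_rel = 0)
    class(fit) <- "wss_mme_fit"
    return(fit)
  }
  lambda <- vc$sigma2_e / vc$sigma2_u
  n <- length(y)
  Zs <- Matrix::sparseMatrix(i = seq_len(n), j = zmap, x = 1,
                             dims = c(n, n_ped))
  Xs <- Matrix::Matrix(X, sparse = TRUE)
  C <- rbind(
    cbind(Matrix::crossprod(Xs), Matrix::crossprod(Xs, Zs)),
    cbind(Matrix::crossprod(Zs, Xs), Matrix::crossprod(Zs) + lambda * Hm)
  )
  rhs <- c(as.numeric(Matrix::crossprod(Xs, y)),
           as.numeric(Matrix::crossprod(Zs, y)))
  sol <- as.numeric(Matrix::solve(C, rhs))
  resid <- as.numeric(C %*% sol) - rhs
  rel <- sqrt(sum(resid^2)) / max(sqrt(sum(rhs^2)), .Machine$double.eps)
  p <- ncol(X)
  fit <- list(
    b_hat = stats::setNames(sol[seq_len(p)], colnames(X)),
    a_hat = stats::setNames(sol[p + seq_len(n_ped)], ids),
    residual_rel = rel
  )
  class(fit) <- "wss_mme_fit"
  fit
}

#' @export
print.wss_mme_fit <- function(x, ...) {
  cat(sprintf("MME solution: %d fixed effects, %d breeding values (rel. residual %.2e)\n",
              length(x$b_hat), length(x$a_hat), x$residual_rel))
  invisible(x)
}
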