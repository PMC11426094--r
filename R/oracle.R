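#' Additive (numerator) relationship matrix by the tabular method
#'
#' Dense recursion: A_ii = 1 + A(sire,dam)/2 and A_ij = (A(j,sire) +
#' A(j,dam))/2 for earlier j; unknown parents contribute 0. Intended for
#' validation at small n — memory is O(n^2).
#'
#' @param ped a [pedigree()].
#' @param max_n refuse pedigrees larger than this (dense matrix guard).
#' @return symmetric matrix with ids as dimnames; diagonal is 1 + F.
#' @export
build_A <- function(ped, max_n = 5000L) {
  n <- nrow(ped)
  if (n > max_n) {
    stop("pedigree has ", n, " individuals; dense A capped at ", max_n,
         " (use inbreeding()/a_inverse() for large pedigrees)")
  }
  pi <- parent_indices(ped)
  s <- pi$sire; d <- pi$dam
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  at <- function(i, j) if (i == 0L || j == 0L) 0 else A[i, j]
  for (i in seq_len(n)) {
    A[i, i] <- 1 + 0.5 * at(s[i], d[i])
    if (i > 1L) {
      for (j in seq_len(i - 1L)) {
        v <- 0.5 * (at(j, s[i]) + at(j, d[i]))
        A[i, j] <- v
        A[j, i] <- v
      }
    }
  }
  A
}

#' Sparse inverse of the additive relationship matrix
#'
#' Henderson's rules with inbreeding: each individual contributes
#' 1/d_i to the (i,i) cell, -0.5/d_i to (i,parent) and 0.25/d_i between
#' parents, where d_i is the Mendelian-sampling variance ratio
#' (1, 0.75 - F_p/4, or 0.5 - (F_s + F_d)/4 for 0, 1, 2 known parents).
#'
#' @param ped a [pedigree()].
#' @param F optional precomputed inbreeding coefficients.
#' @return a sparse symmetric [Matrix::Matrix] with ids as dimnames.
#' @export
a_inverse <- function(ped, F = inbreeding(ped)) {
  pi <- parent_indices(ped)
  s <- pi$sire; d <- pi$dam
  n <- nrow(ped)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  push <- function(i, j, x) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, x)
  }
  Fs <- ifelse(s > 0L, F[pmax(s, 1L)], 0)
  Fd <- ifelse(d > 0L, F[pmax(d, 1L)], 0)
  npar <- (s > 0L) + (d > 0L)
  dvec <- ifelse(npar == 2L, 0.5 - 0.25 * (Fs + Fd),
          ifelse(npar == 1L, 0.75 - 0.25 * ifelse(s > 0L, Fs, Fd), 1))
  for (i in seq_len(n)) {
    w <- 1 / dvec[i]
    push(i, i, w)
    for (p in c(s[i], d[i])) {
      if (p > 0L) {
        push(i, p, -0.5 * w)
        push(p, i, -0.5 * w)
        push(p, p, 0.25 * w)
      }
    }
    if (s[i] > 0L && d[i] > 0L && s[i] != d[i]) {
      push(s[i], d[i], 0.25 * w)
      push(d[i], s[i], 0.25 * w)
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                       dimnames = list(ped$id, ped$id))
}

#' Exact mixed-model fit (GLS and Henderson's MME)
#'
#' Reference solver for the animal model y = Xb + Za + e with
#' var(a) = sigma_a2 * A and var(e) = sigma_e2 * I. Solves the fixed
#' effects twice — by generalized least squares through the inverse of
#' V = sigma_a2 ZAZ' + sigma_e2 I, and by Henderson's mixed model
#' equations — and returns both, along with the polygenic BLUP. The two
#' fixed-effect solutions agree (every estimable function does); dense
#' linear algebra, so n is capped.
#'
#' @param y numeric response vector (length n).
#' @param X fixed-effect design matrix (n x p); may be rank-deficient,
#'   in which case only estimable functions of `b` are unique.
#' @param Z incidence matrix mapping observations to pedigree
#'   individuals (n x q).
#' @param A additive relationship matrix (q x q), e.g. from [build_A()].
#' @param sigma_a2,sigma_e2 additive and residual variance components.
#' @param max_n guard on n for the dense solve.
#' @return list with `b_gls`, `b_mme` (fixed-effect solutions), `a_hat`
#'   (BLUP of a), `vcov_b` (GLS (X'V^-1 X)^-), and the inputs' sizes.
#' @export
exact_fit <- function(y, X, Z, A, sigma_a2, sigma_e2, max_n = 2000L) {
  y <- as.numeric(y)
  X <- as.matrix(X); Z <- as.matrix(Z); A <- as.matrix(A)
  n <- length(y)
  if (n > max_n) stop("exact_fit is a dense reference solver; n capped at ", max_n)
  if (nrow(X) != n || nrow(Z) != n) stop("dimension mismatch between y, X, Z")
  if (sigma_a2 <= 0 || sigma_e2 <= 0) stop("variance components must be > 0")
  V <- sigma_a2 * Z %*% A %*% t(Z) + diag(sigma_e2, n)
  Vi <- solve(V)
  XtVi <- crossprod(X, Vi)
  G <- MASS::ginv(XtVi %*% X)
  b_gls <- drop(G %*% (XtVi %*% y))

  # Henderson's MME
  lambda <- sigma_e2 / sigma_a2
  Ainv <- solve(A)
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + lambda * Ainv))
  rhs <- c(crossprod(X, y), crossprod(Z, y))
  sol <- drop(MASS::ginv(C) %*% rhs)
  p <- ncol(X)
  b_mme <- sol[seq_len(p)]
  a_hat <- sol[-seq_len(p)]
  names(a_hat) <- colnames(Z)
  list(b_gls = b_gls, b_mme = b_mme, a_hat = a_hat, vcov_b = G,
       n = n, p = p, q = ncol(Z), lambda = lambda)
}
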