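## --- internal symmetrized eigensolver -------------------------------------
##
## Both generator kinds are reversible: diag(mu) P is symmetric for the
## stored stationaryWeight mu.  Hence S = diag(sqrt(mu)) P diag(1/sqrt(mu))
## is symmetric with the same (real) eigenvalues as P, and a P-eigenvector
## is recovered as v = u / sqrt(mu).  Dense problems use LAPACK directly;
## larger ones use ARPACK (igraph) with a deterministic start vector.

symTopEigs <- function(L, eps, mu, nev, denseLimit = 1200L) {
  m <- nrow(L)
  if (nev > m) stop("more eigenpairs requested than matrix size")
  smu <- sqrt(mu)
  if (m <= denseLimit || nev > m / 4) {
    P <- if (is(L, "Matrix")) as.matrix(L) * eps else L * eps
    diag(P) <- diag(P) + 1
    S <- P * smu / rep(smu, each = m)
    S <- (S + t(S)) / 2
    es <- eigen(S, symmetric = TRUE)
    s <- es$values[seq_len(nev)]
    U <- es$vectors[, seq_len(nev), drop = FALSE]
  } else {
    matvec <- function(x, extra = NULL) {
      y <- x / smu
      y <- as.numeric(L %*% y) * eps + y
      y * smu
    }
    opts <- igraph::arpack_defaults()
    opts$n <- m
    opts$nev <- nev
    opts$ncv <- min(m, max(4L * nev + 10L, 25L))
    opts$which <- "LA"
    opts$maxiter <- 5000L
    opts$tol <- 1e-12
    opts$start <- cos(seq_len(m))       # fixed start: reproducible runs
    res <- tryCatch(
      igraph::arpack(matvec, sym = TRUE, options = opts),
      error = function(e)
        stop(sprintf("eigensolver failed to converge (m=%d, nev=%d): %s",
                     m, nev, conditionMessage(e))))
    ord <- order(res$values, decreasing = TRUE)
    s <- res$values[ord]
    U <- as.matrix(res$vectors)[, ord, drop = FALSE]
  }
  V <- U / smu
  nrm <- sqrt(colSums(V^2))
  V <- V / rep(nrm, each = m)
  ## sign convention: largest-magnitude entry positive
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  list(lambda = (s - 1) / eps, vectors = V)
}

## infinity norm of the generator (for residual scaling)
opNormInf <- function(L) {
  if (is(L, "Matrix")) max(Matrix::rowSums(abs(L))) else max(rowSums(abs(L)))
}

#' Spectral decomposition of a generator matrix
#'
#' Computes the k+1 eigenvalues closest to zero (the dominant spectrum
#' \eqn{0 = \lambda_0 > \lambda_1 \ge \ldots \ge \lambda_k}) and the
#' matching eigenvectors of a \code{\linkS4class{GeneratorMatrix}}.  The
#' generator is reversible with respect to its stored stationary weight,
#' so the eigenproblem is solved in exact-symmetric form (real
#' eigenvalues by construction); eigenvectors are returned with unit
#' 2-norm and sign fixed so the largest-magnitude entry is positive.
#' Each returned pair is verified against the residual bound
#' \eqn{\|Lv - \lambda v\| \le 10^{-8}\,\|L\|_\infty}.
#'
#' @param generator a \code{\linkS4class{GeneratorMatrix}}.
#' @param k number of nontrivial eigenpairs (1 <= k < m); k+1 pairs are
#'   returned including the trivial constant mode.
#' @return a \code{\linkS4class{SpectralDecomposition}}.
#' @export
spectralDecompose <- function(generator, k) {
  stopifnot(is(generator, "GeneratorMatrix"))
  m <- nrow(generator@values)
  if (k < 1 || k >= m) stop("k must satisfy 1 <= k < m")
  res <- symTopEigs(generator@values, generator@epsilon,
                    generator@stationaryWeight, k + 1L)
  nrmL <- opNormInf(generator@values)
  resid <- vapply(seq_len(k + 1L), function(j) {
    v <- res$vectors[, j]
    sqrt(sum((as.numeric(generator@values %*% v) - res$lambda[j] * v)^2))
  }, numeric(1L))
  if (any(resid > 1e-8 * nrmL))
    stop(sprintf(
      "eigenpair residual %.3g exceeds 1e-8 * ||L|| = %.3g; eigensolver did not converge",
      max(resid), 1e-8 * nrmL))
  new("SpectralDecomposition", values = res$lambda, vectors = res$vectors,
      epsilon = generator@epsilon, residuals = resid)
}

#' Nystrom out-of-sample extension of an eigenvector
#'
#' Extends the j-th eigenvector of an alpha-normalized generator to new
#' points via the kernel row re-evaluated at the new point:
#' \deqn{\psi_j(x) = (1 + \epsilon\lambda_j)^{-1}
#'   \sum_i w(x, x_i)\,[\psi_j]_i,}
#' where \eqn{w(x, \cdot)} is the same density-normalized, row-normalized
#' kernel row used in building \eqn{P_\epsilon}, and
#' \eqn{1 + \epsilon\lambda_j} is the corresponding Markov-matrix
#' eigenvalue.  With this choice the extension is exact at the training
#' points (it reduces to the eigen-equation there).
#'
#' @param decomposition a \code{\linkS4class{SpectralDecomposition}}.
#' @param generator the \code{\linkS4class{GeneratorMatrix}} that was
#'   decomposed (supplies epsilon, alpha and the training density).
#' @param cloud the training \code{\linkS4class{PointCloud}} (or matrix).
#' @param newPoints n x d matrix of points to extend to.
#' @param j eigenvector index (0 = trivial constant mode).
#' @param cutoff kernel cutoff used in training (entries below it are
#'   dropped when re-evaluating the row).
#' @return numeric vector of length n with the extended eigenvector
#'   values.
#' @export
nystromExtend <- function(decomposition, generator, cloud, newPoints, j,
                          cutoff = 0) {
  stopifnot(is(decomposition, "SpectralDecomposition"),
            is(generator, "GeneratorMatrix"))
  if (generator@kind != "alpha_normalized")
    stop("Nystrom extension is implemented for alpha-normalized generators")
  X <- asCoordMatrix(cloud)
  Y <- if (is.matrix(newPoints)) newPoints else
    matrix(newPoints, ncol = ncol(X))
  eps <- generator@epsilon
  lam <- decomposition@values[j + 1L]
  pj <- 1 + eps * lam
  if (abs(pj) < 1e-12)
    stop("Markov eigenvalue 1 + eps*lambda_j vanishes; cannot extend")
  psi <- decomposition@vectors[, j + 1L]
  alpha <- generator@alpha
  qTrain <- generator@q
  D2 <- outer(rowSums(Y^2), rowSums(X^2), "+") - 2 * tcrossprod(Y, X)
  D2[D2 < 0] <- 0
  Kx <- exp(-D2 / (4 * eps))
  if (cutoff > 0) Kx[Kx < cutoff] <- 0
  ## row sums over the training points only; at a training point this
  ## reproduces the training q (the coincident column is the self term),
  ## which is what makes the extension exact there
  qx <- rowSums(Kx)
  W <- Kx * (qx^(-alpha)) * rep(qTrain^(-alpha), each = nrow(Y))
  ext <- as.numeric(W %*% psi) / rowSums(W)
  ext / pj
}
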