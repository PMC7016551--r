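## --- Chebyshev collocation primitives -------------------------------------
##
## Standard Chebyshev-Gauss-Lobatto differentiation matrix and
## Clenshaw-Curtis quadrature weights on [-1, 1] (nodes decreasing,
## x_j = cos(j pi / n), j = 0..n), mapped affinely to [a, b].

chebNodesDiff <- function(n, a = -1, b = 1) {
  stopifnot(n >= 2)
  x <- cos(pi * (0:n) / n)
  c0 <- c(2, rep(1, n - 1L), 2) * (-1)^(0:n)
  X <- matrix(x, n + 1L, n + 1L)
  dX <- X - t(X)
  D <- outer(c0, 1 / c0) / (dX + diag(n + 1L))
  diag(D) <- diag(D) - rowSums(D)
  scale <- (b - a) / 2
  list(x = (a + b) / 2 + scale * x, D = D / scale)
}

clencurtWeights <- function(n, a = -1, b = 1) {
  ## Clenshaw-Curtis weights for nodes cos(j pi / n)
  theta <- pi * (0:n) / n
  w <- numeric(n + 1L)
  v <- rep(1, n - 1L)
  if (n %% 2 == 0) {
    w[1L] <- w[n + 1L] <- 1 / (n^2 - 1)
    for (k in seq_len(n / 2 - 1L))
      v <- v - 2 * cos(2 * k * theta[2:n]) / (4 * k^2 - 1)
    v <- v - cos(n * theta[2:n]) / (n^2 - 1)
  } else {
    w[1L] <- w[n + 1L] <- 1 / n^2
    for (k in seq_len((n - 1L) / 2))
      v <- v - 2 * cos(2 * k * theta[2:n]) / (4 * k^2 - 1)
  }
  w[2:n] <- 2 * v / n
  w * (b - a) / 2
}

## time-rescaled generator  L = d^2/dx^2 - beta V'(x) d/dx  on the grid
chebOperator <- function(potential, beta, a, b, n) {
  nd <- chebNodesDiff(n, a, b)
  gradV <- gradientAt(potential, matrix(nd$x, ncol = 1L))[, 1L]
  A <- nd$D %*% nd$D - beta * gradV * nd$D
  list(x = nd$x, A = A)
}

## Schroedinger-conjugated form of the same generator:
##   H = e^{-beta V/2} L e^{+beta V/2} = d^2/dx^2 - W(x),
##   W = (beta V')^2/4 - beta V''/2,
## with identical spectrum.  The first-order drift term is gone, so the
## collocation matrix is only mildly non-normal and its dominant
## eigenvectors are reliable even when exp(beta V) spans hundreds of
## orders of magnitude across the domain (large domains, steep wells),
## where the drift form loses the eigenvector entirely.  V'' is obtained
## spectrally by differentiating V' on the grid.
chebSchrodinger <- function(potential, beta, a, b, n) {
  nd <- chebNodesDiff(n, a, b)
  gradV <- gradientAt(potential, matrix(nd$x, ncol = 1L))[, 1L]
  hessV <- as.numeric(nd$D %*% gradV)
  W <- (beta * gradV)^2 / 4 - beta * hessV / 2
  H <- nd$D %*% nd$D
  diag(H) <- diag(H) - W
  list(x = nd$x, H = H,
       halfV = beta * energyAt(potential, matrix(nd$x, ncol = 1L)) / 2)
}

#' Chebyshev pseudo-spectral Dirichlet eigenproblem in one dimension
#'
#' Discretizes the time-rescaled generator of overdamped Langevin
#' dynamics, \eqn{L = -\beta V'\,\partial + \partial^2} (the same time
#' scaling that the point-cloud generator approximates, so eigenvalues
#' are directly comparable), with Chebyshev collocation on
#' Gauss--Lobatto nodes, imposes homogeneous Dirichlet conditions at the
#' interval endpoints by restriction to the interior nodes, and returns
#' the k eigenpairs closest to zero.
#'
#' Spectral accuracy is verified by re-solving on a doubled grid; when
#' the first eigenvalue moves by more than 1e-6 the result is marked
#' unconverged.
#'
#' @param potential a \code{\linkS4class{Potential}} (1D).
#' @param beta inverse temperature.
#' @param interval numeric c(a, b).
#' @param n polynomial degree (>= 16); the grid has n+1 nodes.
#' @param k number of eigenpairs to return.
#' @param checkConvergence logical; re-solve on a doubled grid.
#' @return list with \code{grid} (n+1 nodes, decreasing), \code{values}
#'   (k negative eigenvalues, decreasing), \code{vectors} ((n+1) x k, zero
#'   at the endpoints, each with unit maximum absolute value), and
#'   \code{converged}.
#' @export
chebyshevDirichlet <- function(potential, beta, interval, n = 256L, k = 1L,
                               checkConvergence = TRUE) {
  stopifnot(n >= 16L, length(interval) == 2L, interval[1] < interval[2])
  if (potential@dimension != 1L)
    stop("the pseudo-spectral solver is one-dimensional")
  res <- chebDirichletCore(potential, beta, interval, n, k)
  converged <- TRUE
  if (checkConvergence) {
    res2 <- chebDirichletCore(potential, beta, interval, 2L * n, 1L)
    converged <- abs(res2$values[1L] - res$values[1L]) <= 1e-6
  }
  list(grid = res$grid, values = res$values, vectors = res$vectors,
       converged = converged)
}

chebDirichletCore <- function(potential, beta, interval, n, k) {
  op <- chebSchrodinger(potential, beta, interval[1], interval[2], n)
  int <- 2:n
  es <- eigen(op$H[int, int])
  ## the physical (dominant) spectrum is real; spurious complex pairs can
  ## appear deep in the collocation spectrum and are discarded
  real <- abs(Im(es$values)) <= 1e-8 * max(abs(Re(es$values)))
  if (sum(real) < k)
    stop("fewer real collocation eigenvalues than requested; increase n")
  es$values[!real] <- -Inf
  vals <- Re(es$values)
  ord <- order(vals, decreasing = TRUE)[seq_len(k)]
  vals <- vals[ord]
  ## undo the conjugation: v = e^{+beta V/2} phi.  Where phi has decayed
  ## to its round-off floor the product is noise amplified by e^{beta V/2},
  ## so v is only reconstructed on nodes where phi is numerically trusted
  ## and set to 0 elsewhere -- those regions carry e^{-beta V} ~ 0
  ## Boltzmann mass and do not enter any downstream quantity
  blow <- exp(pmin(op$halfV, 500))
  vecs <- matrix(0, n + 1L, k)
  for (j in seq_len(k)) {
    phi <- numeric(n + 1L)
    phi[int] <- Re(es$vectors[, ord[j]])
    trusted <- abs(phi) >= 1e-13 * max(abs(phi))
    v <- ifelse(trusted, phi * blow, 0)
    i <- which.max(abs(v))
    vecs[, j] <- v / v[i]
  }
  list(grid = op$x, values = vals, vectors = vecs)
}

#' Chebyshev pseudo-spectral committor in one dimension
#'
#' Solves \eqn{Lq = 0} on \eqn{(a, b)} with \eqn{q(a) = 0},
#' \eqn{q(b) = 1} for \eqn{L = -\beta V'\partial + \partial^2} by
#' collocation.  For flat potentials the solution is the linear ramp; in
#' general it matches the quadrature closed form
#' \eqn{q(x) = \int_a^x e^{\beta V} / \int_a^b e^{\beta V}}.
#'
#' @param potential a 1D \code{\linkS4class{Potential}}.
#' @param beta inverse temperature.
#' @param a,b boundary points (committor 0 at \code{a}, 1 at \code{b}).
#' @param n polynomial degree.
#' @return list with \code{grid} (decreasing nodes) and \code{values}.
#' @export
chebyshevCommittor <- function(potential, beta, a, b, n = 256L) {
  stopifnot(n >= 16L, a < b)
  op <- chebOperator(potential, beta, a, b, n)
  int <- 2:n
  ## grid is decreasing: node 1 is x = b (q = 1), node n+1 is x = a (q = 0)
  rhs <- -op$A[int, 1L] * 1
  qint <- solve(op$A[int, int], rhs)
  q <- c(1, as.numeric(qint), 0)
  list(grid = op$x, values = q)
}

#' Quasi-stationary distribution from a Dirichlet eigenfunction
#'
#' Given the first Dirichlet eigenfunction \eqn{v} on a Chebyshev grid,
#' forms the QSD density with respect to Lebesgue measure,
#' \deqn{\nu(x) = \frac{v(x)\,e^{-\beta V(x)}}
#'   {\int_\Omega v\,e^{-\beta V}},}
#' and renormalizes \eqn{v} so its mean against the Boltzmann measure
#' restricted to \eqn{\Omega} equals 1 -- with this convention
#' \eqn{v \to 1} pointwise on compacts as the domain grows, which makes
#' the convergence of the QSD to the Boltzmann measure directly
#' observable.  Integrals use Clenshaw--Curtis quadrature on the grid.
#'
#' @param v eigenfunction values on the grid (positive in the interior),
#'   or a function to evaluate there.
#' @param grid Chebyshev--Gauss--Lobatto nodes (decreasing, endpoints
#'   included) as returned by \code{\link{chebyshevDirichlet}}.
#' @param potential,beta potential and inverse temperature defining the
#'   Boltzmann factor.
#' @param lambda1 optional first exit rate to carry along.
#' @return a \code{\linkS4class{QSDResult}}.
#' @export
qsdDensity <- function(v, grid, potential, beta, lambda1 = NA_real_) {
  if (is.function(v)) v <- v(grid)
  n <- length(grid) - 1L
  a <- min(grid); b <- max(grid)
  w <- clencurtWeights(n, a, b)
  interior <- seq(2L, n)
  tol <- 1e-10 * max(abs(v))
  if (any(v[interior] < -tol))
    stop("v must be positive in the interior of the domain")
  v[v < 0] <- 0        # roundoff-level negatives deep in the tails
  boltz <- exp(-beta * energyAt(potential, matrix(grid, ncol = 1L)))
  zOmega <- sum(w * boltz)
  vMean <- sum(w * v * boltz) / zOmega
  v <- v / vMean                       # unit Boltzmann-restricted mean
  nuRaw <- v * boltz
  nu <- nuRaw / sum(w * nuRaw)
  new("QSDResult", grid = as.numeric(grid), v = as.numeric(v),
      nu = as.numeric(nu), lambda1 = lambda1, interval = c(a, b),
      quadWeights = w, converged = TRUE)
}

#' Pseudo-spectral QSD of a 1D potential on a symmetric interval
#'
#' Convenience wrapper: solves the first Dirichlet eigenpair of
#' \eqn{-\beta V'\partial + \partial^2} on \eqn{[-L, L]} (or a general
#' interval) and forms the QSD via \code{\link{qsdDensity}}.
#'
#' @param potential a 1D \code{\linkS4class{Potential}}.
#' @param beta inverse temperature.
#' @param L half-width of the symmetric domain \eqn{[-L, L]}; ignored
#'   when \code{interval} is given.
#' @param interval optional explicit interval c(a, b).
#' @param n polynomial degree.
#' @return a \code{\linkS4class{QSDResult}} (with \code{converged}
#'   reflecting the doubled-grid check).
#' @export
chebyshevQSD <- function(potential, beta, L = NULL, interval = NULL,
                         n = 256L) {
  if (is.null(interval)) {
    stopifnot(!is.null(L), L > 0)
    interval <- c(-L, L)
  }
  ed <- chebyshevDirichlet(potential, beta, interval, n = n, k = 1L)
  v <- ed$vectors[, 1L]
  if (mean(v[2:(length(v) - 1L)]) < 0) v <- -v
  out <- qsdDensity(v, ed$grid, potential, beta, lambda1 = -ed$values[1L])
  out@converged <- ed$converged
  out
}

#' Evaluate a QSD eigenfunction at arbitrary points
#'
#' Interpolates \eqn{v} through the identity \eqn{v = \nu Z_\Omega /
#' e^{-\beta V}} (with \eqn{\nu} the QSD density and \eqn{Z_\Omega} the
#' restricted partition function): \eqn{\nu} is smooth all the way into
#' the tails, so this route avoids the noise amplification of
#' interpolating \eqn{v} directly where the Boltzmann factor spans many
#' orders of magnitude.  Only meaningful where \eqn{e^{-\beta V(x)}} is
#' not negligible.
#'
#' @param qsd a \code{\linkS4class{QSDResult}}.
#' @param potential,beta the potential and inverse temperature the QSD
#'   was solved with.
#' @param x evaluation points.
#' @return numeric vector of \eqn{v(x)} values.
#' @export
qsdEigenfunctionAt <- function(qsd, potential, beta, x) {
  boltz <- exp(-beta * energyAt(potential, matrix(qsd@grid, ncol = 1L)))
  zOmega <- sum(qsd@quadWeights * boltz)
  nuX <- chebInterp(qsd@grid, qsd@nu, x)
  nuX * zOmega / exp(-beta * energyAt(potential, matrix(x, ncol = 1L)))
}

#' Barycentric interpolation from a Chebyshev grid
#'
#' Evaluates a grid solution (eigenfunction, committor, QSD density) at
#' arbitrary points by barycentric Lagrange interpolation.
#'
#' @param grid interpolation nodes.
#' @param values values on the nodes.
#' @param xout evaluation points (inside the node range).
#' @return numeric vector of interpolated values.
#' @export
chebInterp <- function(grid, values, xout) {
  ord <- order(grid)
  pracma::barylag(grid[ord], values[ord], xout)
}
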