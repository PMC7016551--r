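#' Build the alpha-normalized graph-Laplacian generator
#'
#' Two-step density normalization followed by the
#' \eqn{\epsilon}-scaled Laplacian: the kernel is first renormalized as
#' \eqn{K^{(\alpha)}_{ij} = K_{ij} / (q_i^\alpha q_j^\alpha)}, then
#' row-normalized into the Markov matrix \eqn{P_\epsilon}, and the
#' generator approximation is
#' \deqn{L_\epsilon = \epsilon^{-1}(P_\epsilon - I).}
#' As \eqn{m \to \infty}, \eqn{\epsilon \to 0} this converges point-wise
#' to \eqn{\Delta f + (2-2\alpha) \nabla f \cdot \nabla\pi/\pi}; for
#' \eqn{\alpha = 1/2} and Boltzmann-sampled data that is
#' \eqn{\beta L_\beta}, the time-rescaled generator of overdamped
#' Langevin dynamics.
#'
#' Note on conventions: a one-step normalization
#' \eqn{P = D_\alpha^{-1} K} with \eqn{D_\alpha = diag(q^{-\alpha})}
#' appears in compressed notations of this construction, but read
#' literally it is not row-stochastic and does not have the limit above;
#' this package implements the standard two-step construction throughout.
#' Because the row normalization divides by the row sums of
#' \eqn{K^{(\alpha)}}, any constant rescaling of \code{q} cancels, so raw
#' kernel row sums are used as the density estimate.
#'
#' @param kernel a \code{\linkS4class{KernelMatrix}}.
#' @param q kernel density estimate (defaults to
#'   \code{kernelDensity(kernel)}).
#' @param alpha density-normalization exponent in [0, 1]; 1/2 targets the
#'   Langevin generator and is the package default throughout.
#' @return a \code{\linkS4class{GeneratorMatrix}} whose rows sum to zero.
#' @export
buildGenerator <- function(kernel, q = kernelDensity(kernel), alpha = 0.5) {
  stopifnot(is(kernel, "KernelMatrix"), alpha >= 0, alpha <= 1)
  K <- kernel@values
  if (any(q <= 0)) stop("density estimate must be strictly positive")
  qa <- q^(-alpha)
  if (is(K, "Matrix")) {
    W <- Diagonal(x = qa) %*% K %*% Diagonal(x = qa)
    checkConnected(W)
    d <- as.numeric(Matrix::rowSums(W))
    if (any(d == 0))
      stop(sprintf("isolated point after cutoff: index %d has a zero kernel row",
                   which(d == 0)[1L]))
    P <- Diagonal(x = 1 / d) %*% W
    L <- (P - Diagonal(nrow(K))) / kernel@epsilon
    L <- methods::as(L, "generalMatrix")
  } else {
    W <- t(K * qa) * qa          # W_ij = K_ij qa_i qa_j, exactly symmetric
    d <- rowSums(W)
    if (any(d == 0))
      stop(sprintf("isolated point after cutoff: index %d has a zero kernel row",
                   which(d == 0)[1L]))
    L <- W / d
    diag(L) <- diag(L) - 1
    L <- L / kernel@epsilon
  }
  new("GeneratorMatrix", values = L, epsilon = kernel@epsilon,
      alpha = alpha, kind = "alpha_normalized", q = as.numeric(q),
      stationaryWeight = as.numeric(d))
}

#' Build the target-measure diffusion map (TMDmap) generator
#'
#' When samples are drawn from a surrogate distribution (e.g. a biased
#' trajectory) but known values of an unnormalized target density
#' \eqn{\pi} are available, the kernel is right-normalized with
#' \eqn{\mathrm{diag}(\pi^{1/2}/q_\epsilon)} and row-normalized by the
#' resulting row sums \eqn{\tilde D}:
#' \deqn{L_{\epsilon,\pi} = \epsilon^{-1}(\tilde D^{-1} K_\epsilon
#'   \mathrm{diag}(\pi^{1/2} q_\epsilon^{-1}) - I),}
#' which converges to \eqn{\nabla \log\pi \cdot \nabla + \Delta}
#' regardless of the sampling distribution.  Any positive rescaling of
#' \eqn{\pi} cancels in the row normalization, so unnormalized target
#' densities are accepted.
#'
#' @param kernel a \code{\linkS4class{KernelMatrix}}.
#' @param q kernel density estimate (defaults to
#'   \code{kernelDensity(kernel)}).
#' @param targetDensity strictly positive values of the (unnormalized)
#'   target density at the sample points.
#' @return a \code{\linkS4class{GeneratorMatrix}} of kind
#'   \code{"tmdmap"}.
#' @export
buildTMDmap <- function(kernel, q = kernelDensity(kernel), targetDensity) {
  stopifnot(is(kernel, "KernelMatrix"))
  if (any(!is.finite(targetDensity)) || any(targetDensity <= 0))
    stop("target density values must be finite and strictly positive")
  if (length(targetDensity) != nrow(kernel@values))
    stop("one target density value per point is required")
  K <- kernel@values
  w <- sqrt(targetDensity) / q
  if (is(K, "Matrix")) {
    Kpi <- K %*% Diagonal(x = w)
    checkConnected(Kpi)
    dtil <- as.numeric(Matrix::rowSums(Kpi))
    if (any(dtil == 0))
      stop(sprintf("isolated point after cutoff: index %d has a zero kernel row",
                   which(dtil == 0)[1L]))
    L <- (Diagonal(x = 1 / dtil) %*% Kpi - Diagonal(nrow(K))) /
      kernel@epsilon
    L <- methods::as(L, "generalMatrix")
  } else {
    Kpi <- t(K * w)              # K symmetric: K diag(w) = t(w * K)
    dtil <- rowSums(Kpi)
    if (any(dtil == 0))
      stop(sprintf("isolated point after cutoff: index %d has a zero kernel row",
                   which(dtil == 0)[1L]))
    L <- Kpi / dtil
    diag(L) <- diag(L) - 1
    L <- L / kernel@epsilon
  }
  ## reversibility: mu_i P_ij = w_i dtil_i^{-1} ... with mu = w * dtil,
  ## mu_i P_ij = w_i K_ij w_j is symmetric
  new("GeneratorMatrix", values = L, epsilon = kernel@epsilon,
      alpha = NA_real_, kind = "tmdmap", q = as.numeric(q),
      stationaryWeight = as.numeric(w * dtil))
}
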