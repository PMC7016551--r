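#' Solve the committor linear system on a point cloud
#'
#' The committor \eqn{q(x)} (probability of reaching B before A) solves
#' \eqn{Lq = 0} outside \eqn{A \cup B} with \eqn{q = 0} on A and
#' \eqn{q = 1} on B.  On the point cloud this is the linear system
#' \deqn{L_\epsilon[c,c]\, q[c] = -L_\epsilon[c,b]\,\mathbf{1},}
#' where \eqn{c} indexes \eqn{C = D \setminus (A \cup B)} and \eqn{b}
#' indexes B; A enters only through its exclusion from \eqn{C}.  Values
#' outside \eqn{[-0.05, 1.05]} (small violations of the maximum principle
#' are possible at finite \eqn{m, \epsilon}) are flagged, never clamped.
#'
#' @param generator a \code{\linkS4class{GeneratorMatrix}}.
#' @param idxA,idxB non-empty disjoint integer index sets.
#' @return a \code{\linkS4class{CommittorField}}.
#' @export
solveCommittor <- function(generator, idxA, idxB) {
  stopifnot(is(generator, "GeneratorMatrix"))
  m <- nrow(generator@values)
  idxA <- sort(unique(as.integer(idxA)))
  idxB <- sort(unique(as.integer(idxB)))
  if (!length(idxA) || !length(idxB)) stop("idxA and idxB must be non-empty")
  if (length(intersect(idxA, idxB))) stop("idxA and idxB must be disjoint")
  idxC <- setdiff(seq_len(m), union(idxA, idxB))
  if (!length(idxC)) stop("the complement C must be non-empty")
  L <- generator@values
  Lcc <- L[idxC, idxC, drop = FALSE]
  rhs <- -if (is(L, "Matrix"))
    as.numeric(Matrix::rowSums(L[idxC, idxB, drop = FALSE]))
  else rowSums(L[idxC, idxB, drop = FALSE])
  sol <- tryCatch(
    as.numeric(solve(Lcc, rhs)),
    error = function(e)
      stop(sprintf(
        "committor subsystem is singular (disconnected block inside C?): %s",
        conditionMessage(e))))
  q <- numeric(m)
  q[idxB] <- 1
  q[idxC] <- sol
  new("CommittorField", values = q, idxA = idxA, idxB = idxB,
      flagged = q < -0.05 | q > 1.05)
}

#' Dirichlet eigenproblem on a point-cloud subdomain
#'
#' Realizes homogeneous Dirichlet boundary conditions on the point cloud
#' by restricting the generator to the principal submatrix
#' \eqn{L_\epsilon[\Omega,\Omega]} of the points inside the domain
#' (equivalent, for vectors supported in \eqn{\Omega}, to zeroing the
#' exterior rows, but better conditioned).  Returns the k eigenpairs
#' closest to zero; Dirichlet conditions remove the zero mode, so all
#' eigenvalues are strictly negative.  Eigenvectors are embedded back
#' into the full cloud with exact zeros outside \eqn{\Omega}.
#'
#' @param generator a \code{\linkS4class{GeneratorMatrix}}.
#' @param domainIdx indices of the points inside \eqn{\Omega}
#'   (|domainIdx| > k).
#' @param k number of eigenpairs.
#' @return a \code{\linkS4class{DirichletSpectrum}}.
#' @export
solveDirichletEigen <- function(generator, domainIdx, k) {
  stopifnot(is(generator, "GeneratorMatrix"))
  m <- nrow(generator@values)
  domainIdx <- sort(unique(as.integer(domainIdx)))
  if (length(domainIdx) <= k)
    stop("domain must contain more points than requested eigenpairs")
  Lsub <- generator@values[domainIdx, domainIdx, drop = FALSE]
  res <- symTopEigs(Lsub, generator@epsilon,
                    generator@stationaryWeight[domainIdx], k)
  vecs <- matrix(0, nrow = m, ncol = k)
  vecs[domainIdx, ] <- res$vectors
  new("DirichletSpectrum", eigenvalues = res$lambda, eigenvectors = vecs,
      domainIdx = domainIdx)
}
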