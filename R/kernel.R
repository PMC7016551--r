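## Accept a PointCloud or a bare matrix of coordinates.
asCoordMatrix <- function(cloud) {
  X <- if (is(cloud, "PointCloud") || is(cloud, "Trajectory")) coords(cloud)
       else as.matrix(cloud)
  if (!is.numeric(X)) stop("coordinates must be numeric")
  if (!all(is.finite(X))) stop("non-finite coordinates")
  X
}

#' Build the Gaussian kernel matrix of a point cloud
#'
#' Evaluates the isotropic kernel
#' \eqn{K_{ij} = \exp(-\|x_i - x_j\|^2 / (4\epsilon))} (Euclidean norm)
#' on all point pairs.  With \code{cutoff = 0} the matrix is dense with
#' exact unit diagonal; with \code{cutoff > 0} entries below the cutoff
#' are dropped symmetrically and the result is stored sparse.  The
#' computation is blocked over rows, so memory stays near one m x m
#' matrix (dense case) or the surviving triplets (sparse case).
#'
#' @param cloud a \code{\linkS4class{PointCloud}} (or bare matrix).
#' @param epsilon kernel bandwidth \eqn{\epsilon > 0}.  No automatic
#'   tuner is provided; see \code{\link{kernelSumDiagnostic}} for the
#'   standard log-log guidance plot data.
#' @param cutoff sparsification threshold (entries < cutoff become 0).
#' @return a \code{\linkS4class{KernelMatrix}}.
#' @examples
#' K <- buildKernel(matrix(c(0, 2), ncol = 1), epsilon = 1)
#' K@values[1, 2]  # exp(-1)
#' @export
buildKernel <- function(cloud, epsilon, cutoff = 0) {
  stopifnot(epsilon > 0, cutoff >= 0)
  X <- asCoordMatrix(cloud)
  m <- nrow(X)
  sq <- rowSums(X^2)
  blocks <- split(seq_len(m), ceiling(seq_len(m) / 1024L))
  if (cutoff == 0) {
    K <- matrix(0, m, m)
    for (idx in blocks) {
      D2 <- outer(sq[idx], sq, "+") - 2 * tcrossprod(X[idx, , drop = FALSE], X)
      D2[D2 < 0] <- 0
      K[idx, ] <- exp(-D2 / (4 * epsilon))
    }
    diag(K) <- 1
    K <- (K + t(K)) / 2   # exact symmetry against blocked round-off
  } else {
    ii <- list(); jj <- list(); xx <- list(); b <- 0L
    for (idx in blocks) {
      D2 <- outer(sq[idx], sq, "+") - 2 * tcrossprod(X[idx, , drop = FALSE], X)
      D2[D2 < 0] <- 0
      Kb <- exp(-D2 / (4 * epsilon))
      keep <- which(Kb >= cutoff, arr.ind = TRUE)
      b <- b + 1L
      ii[[b]] <- idx[keep[, 1L]]
      jj[[b]] <- keep[, 2L]
      xx[[b]] <- Kb[keep]
    }
    K <- sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                      dims = c(m, m))
    K <- (K + Matrix::t(K)) / 2
  }
  new("KernelMatrix", values = K, epsilon = epsilon, cutoff = cutoff)
}

#' Kernel density estimate
#'
#' The kernel density estimate at each sample is the corresponding row
#' sum of the kernel matrix, \eqn{q_i = \sum_j K_{ij}} (self term
#' included, so \eqn{q_i \ge 1} when \code{cutoff = 0}).
#'
#' @param kernel a \code{\linkS4class{KernelMatrix}}.
#' @return numeric vector of positive density estimates.
#' @export
kernelDensity <- function(kernel) {
  stopifnot(is(kernel, "KernelMatrix"))
  as.numeric(Matrix::rowSums(kernel@values))
}

#' Kernel-sum diagnostic for choosing epsilon
#'
#' Returns the data of the standard log-log diagnostic: the total kernel
#' sum \eqn{S(\epsilon) = \sum_{ij} K_{ij}} over a grid of bandwidths.
#' In the well-scaled regime the slope of \eqn{\log S} versus
#' \eqn{\log \epsilon} approaches d/2 (the intrinsic dimension over two),
#' and \eqn{\epsilon} is typically chosen inside that regime.
#'
#' @param cloud a \code{\linkS4class{PointCloud}} (or matrix).
#' @param epsilons grid of bandwidths to scan.
#' @return data.frame with columns \code{epsilon} and \code{kernelSum}.
#' @export
kernelSumDiagnostic <- function(cloud, epsilons) {
  X <- asCoordMatrix(cloud)
  sq <- rowSums(X^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  D2[D2 < 0] <- 0
  data.frame(epsilon = epsilons,
             kernelSum = vapply(epsilons,
                                function(e) sum(exp(-D2 / (4 * e))),
                                numeric(1L)))
}

## Connected components of the kernel graph (sparse pattern); errors with
## the component list when the graph is disconnected.
checkConnected <- function(W) {
  if (!is(W, "Matrix")) return(invisible(TRUE))  # dense Gaussian: connected
  g <- igraph::graph_from_adjacency_matrix(W != 0, mode = "undirected")
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    sizes <- paste(comp$csize, collapse = ", ")
    stop(sprintf(
      "kernel graph is disconnected after cutoff: %d components (sizes %s); decrease the cutoff or increase epsilon",
      comp$no, sizes))
  }
  invisible(TRUE)
}
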