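#' Extract the coordinate matrix
#'
#' Returns the m x d matrix of configurations stored in a point cloud,
#' trajectory or replica ensemble.
#'
#' @param x a \code{PointCloud}, \code{Trajectory} or
#'   \code{ReplicaEnsemble}.
#' @return numeric matrix, one configuration per row.
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname coords
#' @export
setMethod("coords", "PointCloud", function(x) x@points)
#' @rdname coords
#' @export
setMethod("coords", "Trajectory", function(x) x@points)
#' @rdname coords
#' @export
setMethod("coords", "ReplicaEnsemble", function(x) x@positions)

#' Number of points
#'
#' @param x an object holding a set of configurations.
#' @return integer count of rows.
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))
#' @rdname nPoints
#' @export
setMethod("nPoints", "PointCloud", function(x) nrow(x@points))
#' @rdname nPoints
#' @export
setMethod("nPoints", "Trajectory", function(x) nrow(x@points))

#' Eigenvalues and eigenvectors
#'
#' Accessors for the spectral containers.  For a
#' \code{SpectralDecomposition}, \code{eigenValues} returns the k+1
#' generator eigenvalues starting at \eqn{\lambda_0 = 0} and
#' \code{eigenVectors} the matching columns; \code{diffusionCoords}
#' drops the trivial constant mode and returns the diffusion-coordinate
#' columns \eqn{(\phi_1, \ldots, \phi_k)}.
#'
#' @param x a \code{SpectralDecomposition} or \code{DirichletSpectrum}.
#' @return numeric vector (values) or matrix (vectors).
#' @export
setGeneric("eigenValues", function(x) standardGeneric("eigenValues"))
#' @rdname eigenValues
#' @export
setGeneric("eigenVectors", function(x) standardGeneric("eigenVectors"))
#' @rdname eigenValues
#' @export
setGeneric("diffusionCoords", function(x) standardGeneric("diffusionCoords"))

#' @rdname eigenValues
#' @export
setMethod("eigenValues", "SpectralDecomposition", function(x) x@values)
#' @rdname eigenValues
#' @export
setMethod("eigenVectors", "SpectralDecomposition", function(x) x@vectors)
#' @rdname eigenValues
#' @export
setMethod("diffusionCoords", "SpectralDecomposition",
          function(x) x@vectors[, -1L, drop = FALSE])
#' @rdname eigenValues
#' @export
setMethod("eigenValues", "DirichletSpectrum", function(x) x@eigenvalues)
#' @rdname eigenValues
#' @export
setMethod("eigenVectors", "DirichletSpectrum", function(x) x@eigenvectors)

#' Committor values accessor
#'
#' @param x a \code{CommittorField}.
#' @return numeric vector of per-point committor values.
#' @export
setGeneric("committorValues", function(x) standardGeneric("committorValues"))
#' @rdname committorValues
#' @export
setMethod("committorValues", "CommittorField", function(x) x@values)

#' @describeIn coords coerce generator matrices to a base matrix
#' @export
setMethod("as.matrix", "GeneratorMatrix", function(x, ...) {
  if (is(x@values, "Matrix")) as.matrix(x@values) else x@values
})

setMethod("show", "Potential", function(object) {
  cat(sprintf("Potential '%s' in dimension %d\n", object@name,
              object@dimension))
  if (length(object@params))
    cat("  params:", paste(names(object@params), unlist(object@params),
                           sep = "=", collapse = ", "), "\n")
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf(
    "Trajectory: %d samples in %dd (dt=%g, beta=%g, scheme=%s, seed=%d)\n",
    nrow(object@points), ncol(object@points), object@dt, object@beta,
    object@scheme, object@seed))
})

setMethod("show", "PointCloud", function(object) {
  cat(sprintf("PointCloud: %d points in %dd%s\n", nrow(object@points),
              ncol(object@points),
              if (length(object@weights)) " (weighted)" else ""))
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

setMethod("show", "KernelMatrix", function(object) {
  cat(sprintf("KernelMatrix: %d x %d, epsilon=%g, cutoff=%g (%s)\n",
              nrow(object@values), ncol(object@values), object@epsilon,
              object@cutoff,
              if (is(object@values, "Matrix")) "sparse" else "dense"))
})

setMethod("show", "GeneratorMatrix", function(object) {
  cat(sprintf("GeneratorMatrix (%s): %d x %d, epsilon=%g%s\n", object@kind,
              nrow(object@values), ncol(object@values), object@epsilon,
              if (object@kind == "alpha_normalized")
                sprintf(", alpha=%g", object@alpha) else ""))
})

setMethod("show", "SpectralDecomposition", function(object) {
  cat(sprintf("SpectralDecomposition: %d eigenpairs on %d points\n",
              length(object@values), nrow(object@vectors)))
  cat("  eigenvalues:",
      paste(signif(utils::head(object@values, 6L), 4L), collapse = ", "),
      if (length(object@values) > 6L) "..." else "", "\n")
})

setMethod("show", "CommittorField", function(object) {
  cat(sprintf(
    "CommittorField: %d points (|A|=%d, |B|=%d), %d flagged outside [-0.05, 1.05]\n",
    length(object@values), length(object@idxA), length(object@idxB),
    sum(object@flagged)))
})

setMethod("show", "QSDResult", function(object) {
  cat(sprintf(
    "QSD on [%g, %g]: lambda1=%.6g, %d Chebyshev nodes%s\n",
    object@interval[1], object@interval[2], object@lambda1,
    length(object@grid),
    if (!object@converged) " [grid not converged]" else ""))
})

setMethod("show", "MetastablePartition", function(object) {
  cat(sprintf(
    "MetastablePartition: |A|=%d (centre %d), |B|=%d (centre %d), threshold=%g\n",
    length(object@membersA), object@centerMax, length(object@membersB),
    object@centerMin, object@threshold))
})

setMethod("show", "SpectrumWindowSeries", function(object) {
  cat(sprintf("SpectrumWindowSeries: %d windows, k=%d; exit %s\n",
              nrow(object@eigenvalues), ncol(object@eigenvalues),
              if (is.na(object@exitFlag)) "not flagged"
              else sprintf("flagged at window %d", object@exitFlag)))
})

setMethod("show", "CVSelection", function(object) {
  cat("CVSelection: chosen\n")
  print(object@chosen)
})

setMethod("show", "AdaptiveRunReport", function(object) {
  cat(sprintf(
    "AdaptiveRunReport: %d iterations, %d transitions%s\n",
    length(object@iterations), object@transitions,
    if (object@inconclusive) " [inconclusive: spectrum did not converge]"
    else ""))
})
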