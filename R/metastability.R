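#' Identify two metastable sets from the first diffusion coordinate
#'
#' The first nontrivial eigenvector \eqn{\phi_1} has (after centring) a
#' sign structure that separates the two most metastable regions and is
#' approximately constant on each.  The set centres are placed at the
#' argmax and argmin of \eqn{\phi_1}; each set is then grown to all
#' points whose Euclidean distance to its centre in the first
#' \code{embeddingDim} diffusion coordinates is below \code{threshold}.
#' A point qualifying for both sets joins the nearer centre (ties go to
#' A, the argmax set).  The raw eigenvector coordinates are used (no
#' \eqn{e^{\lambda t}} weighting; the user-set threshold absorbs the
#' scale).
#'
#' @param decomposition a \code{\linkS4class{SpectralDecomposition}} with
#'   at least 2 eigenvectors.
#' @param threshold growth radius in diffusion space (>= 0; 0 keeps just
#'   the centres).
#' @param embeddingDim number of diffusion coordinates for the distance
#'   (default 1).
#' @return a \code{\linkS4class{MetastablePartition}}.
#' @export
identifyMetastableSets <- function(decomposition, threshold,
                                   embeddingDim = 1L) {
  stopifnot(is(decomposition, "SpectralDecomposition"), threshold >= 0)
  V <- decomposition@vectors
  if (ncol(V) < 2L) stop("decomposition must provide >= 2 eigenvectors")
  embeddingDim <- min(as.integer(embeddingDim), ncol(V) - 1L)
  phi1 <- V[, 2L]
  if (sd(phi1) < 1e-8 * (max(abs(phi1)) + 1e-300))
    stop(paste("phi_1 is numerically constant (no spectral gap resolved);",
               "more data or a different epsilon is needed"))
  iMax <- which.max(phi1)
  iMin <- which.min(phi1)
  E <- V[, 1L + seq_len(embeddingDim), drop = FALSE]
  dA <- sqrt(rowSums((E - rep(E[iMax, ], each = nrow(E)))^2))
  dB <- sqrt(rowSums((E - rep(E[iMin, ], each = nrow(E)))^2))
  inA <- dA < threshold | seq_along(dA) == iMax
  inB <- dB < threshold | seq_along(dB) == iMin
  both <- inA & inB
  ## nearest centre wins; exact ties broken toward A
  inB[both & dA <= dB] <- FALSE
  inA[both & dA > dB] <- FALSE
  new("MetastablePartition",
      centerMax = iMax, centerMin = iMin,
      membersA = which(inA), membersB = which(inB),
      threshold = threshold, embeddingDim = embeddingDim)
}

#' Flag an exit in a series of window spectra
#'
#' Given per-window dominant eigenvalues, computes the per-window mean
#' and maximal successive difference, and flags the first window whose
#' mean changes from the previous window by more than \code{jumpFactor}
#' times the standard deviation of the preceding (converged) window
#' means.  No numeric trigger is canonical for this detector, so both
#' raw series are returned for users who prefer their own rule.
#'
#' @param eigenvalueWindows W x k matrix (or list of length-k vectors):
#'   row w holds the dominant nonzero eigenvalues of window w, sorted
#'   decreasingly.
#' @param jumpFactor detection multiplier (default 5).
#' @param steps optional window start step indices.
#' @return a \code{\linkS4class{SpectrumWindowSeries}}.
#' @export
flagSpectrumExit <- function(eigenvalueWindows, jumpFactor = 5,
                             steps = NULL) {
  E <- if (is.list(eigenvalueWindows)) do.call(rbind, eigenvalueWindows)
       else as.matrix(eigenvalueWindows)
  W <- nrow(E)
  means <- rowMeans(E)
  maxdiffs <- apply(E, 1L, function(ev)
    if (length(ev) > 1L) max(abs(diff(sort(ev)))) else 0)
  exitFlag <- NA_integer_
  if (W >= 3L) {
    for (w in 3:W) {
      jump <- abs(means[w] - means[w - 1L])
      trail <- sd(means[seq_len(w - 1L)])
      if (jump > jumpFactor * trail && jump > 0) {
        exitFlag <- w
        break
      }
    }
  }
  if (is.null(steps)) steps <- seq_len(W)
  new("SpectrumWindowSeries", steps = as.integer(steps), eigenvalues = E,
      means = means, maxdiffs = maxdiffs, exitFlag = exitFlag,
      jumpFactor = jumpFactor)
}

#' Monitor the diffusion-map spectrum along a trajectory
#'
#' Splits the trajectory into successive windows of
#' \code{windowSize * subsample} steps, draws \code{windowSize} points
#' from each by uniform-stride subsampling, builds the
#' \eqn{\alpha = 1/2} generator on each window and records its k
#' dominant nonzero eigenvalues.  While the process is trapped in a
#' metastable state the window spectra approximate the (QSD-weighted)
#' generator of that state and stabilize; an exit changes the sampled
#' operator and shows up as a jump in the mean eigenvalue, which
#' \code{\link{flagSpectrumExit}} detects.
#'
#' @param trajectory a \code{\linkS4class{Trajectory}} or coordinate
#'   matrix.
#' @param windowSize points per window (after subsampling).
#' @param subsample stride within the window
#'   (\code{windowSize * subsample} trajectory steps per window).
#' @param k number of dominant nonzero eigenvalues tracked.
#' @param eps kernel bandwidth for the per-window generator.
#' @param jumpFactor exit-detection multiplier (see
#'   \code{\link{flagSpectrumExit}}).
#' @param cutoff kernel cutoff for the per-window generator.
#' @return a \code{\linkS4class{SpectrumWindowSeries}}.
#' @export
spectrumMonitor <- function(trajectory, windowSize, subsample, k, eps,
                            jumpFactor = 5, cutoff = 0) {
  X <- if (is(trajectory, "Trajectory")) trajectory@points
       else as.matrix(trajectory)
  span <- windowSize * subsample
  if (span > nrow(X))
    stop("window_size * subsample exceeds the trajectory length")
  nW <- nrow(X) %/% span
  ev <- matrix(NA_real_, nW, k)
  steps <- integer(nW)
  for (w in seq_len(nW)) {
    rows <- seq.int((w - 1L) * span + 1L, w * span, by = subsample)
    steps[w] <- rows[1L]
    Xw <- X[rows, , drop = FALSE]
    gen <- buildGenerator(buildKernel(Xw, eps, cutoff), alpha = 0.5)
    dec <- spectralDecompose(gen, k)
    ev[w, ] <- dec@values[-1L]
  }
  flagSpectrumExit(ev, jumpFactor = jumpFactor, steps = steps)
}

#' Correlation of the first diffusion coordinate with each coordinate
#'
#' Pearson correlation of \eqn{\phi_1} against every column of the
#' configuration matrix.  Inside a metastable state the first diffusion
#' coordinate parametrizes the slowest local mode (e.g. the transverse
#' coordinate of a narrow well); on a globally explored cloud it
#' parametrizes the slowest global transition.  Zero-variance columns
#' yield \code{NA} rather than an error.
#'
#' @param decomposition a \code{\linkS4class{SpectralDecomposition}}.
#' @param coordinates m x d matrix of the same points.
#' @return numeric vector of length d of correlations (NA where
#'   undefined).
#' @export
localGlobalDCCorrelation <- function(decomposition, coordinates) {
  stopifnot(is(decomposition, "SpectralDecomposition"))
  X <- as.matrix(coordinates)
  if (nrow(X) != nrow(decomposition@vectors))
    stop("coordinate rows must match the decomposition")
  phi1 <- decomposition@vectors[, 2L]
  vapply(seq_len(ncol(X)), function(j) {
    if (sd(X[, j]) == 0) return(NA_real_)
    cor(phi1, X[, j])
  }, numeric(1L))
}
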