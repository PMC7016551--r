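#' Pearson correlation coefficient
#'
#' \eqn{\rho(X,Y) = \mathrm{cov}(X,Y) / (\sigma_X \sigma_Y)} with
#' population (1/m) conventions; the normalization cancels, so the value
#' coincides with the usual sample correlation.  Errors (naming the
#' degenerate input) on zero variance.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return correlation in [-1, 1].
#' @export
pearsonCorrelation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (sd(x) == 0) stop("first input has zero variance")
  if (sd(y) == 0) stop("second input has zero variance")
  as.numeric(cor(x, y))
}

#' Assemble a candidate collective-variable set
#'
#' Evaluates each candidate CV along the sample and stores the evaluator
#' functions for on-the-fly use during biased dynamics.  Each evaluator
#' may be a function (finite-difference gradient when biased) or a
#' \code{list(value=, grad=)} pair with an exact gradient.
#'
#' @param samples m x d matrix of configurations.
#' @param evaluators named list of candidate CVs.
#' @return a \code{\linkS4class{CandidateCVSet}}.
#' @export
candidateCVSet <- function(samples, evaluators) {
  X <- as.matrix(samples)
  stopifnot(length(evaluators) >= 1L, !is.null(names(evaluators)))
  d <- ncol(X)
  evs <- lapply(evaluators, asCV, d = d)
  vals <- vapply(evs, function(cv) apply(X, 1L, cv$value),
                 numeric(nrow(X)))
  new("CandidateCVSet", cvNames = names(evaluators),
      values = as.matrix(vals), evaluators = evs)
}

#' Coordinate-projection candidate CVs for toy systems
#'
#' The standard candidate list for the 2D toy systems: the coordinate
#' projections x and y, their linear combinations x+y and x-y, and a
#' synthetic pure-noise control.  The noise candidate is a seeded
#' nearest-neighbour lookup into an i.i.d. Gaussian table on reference
#' points: a deterministic function of the configuration that reproduces
#' its stored values, is uncorrelated with any smooth coordinate, and is
#' piecewise constant (zero gradient almost everywhere), so biasing along
#' it exerts no systematic force -- the negative control of the CV
#' selection.
#'
#' @param samples m x 2 matrix used both to evaluate the candidates and
#'   as the noise lookup table's reference points.
#' @param seed seed of the noise table.
#' @param includeNoise include the pure-noise control candidate.
#' @return a \code{\linkS4class{CandidateCVSet}} with candidates
#'   \code{x}, \code{y}, \code{x+y}, \code{x-y} (+ \code{noise}).
#' @export
toyCandidateCVs <- function(samples, seed = 1L, includeNoise = TRUE) {
  X <- as.matrix(samples)
  stopifnot(ncol(X) == 2L)
  evs <- list(
    `x`   = list(value = function(p) p[1], grad = function(p) c(1, 0)),
    `y`   = list(value = function(p) p[2], grad = function(p) c(0, 1)),
    `x+y` = list(value = function(p) p[1] + p[2],
                 grad = function(p) c(1, 1)),
    `x-y` = list(value = function(p) p[1] - p[2],
                 grad = function(p) c(1, -1)))
  if (includeNoise) {
    set.seed(deriveSeed(seed, 17L))
    tab <- rnorm(nrow(X))
    ref <- X
    noiseValue <- function(p) {
      i <- which.min((ref[, 1] - p[1])^2 + (ref[, 2] - p[2])^2)
      tab[i]
    }
    evs$noise <- list(value = noiseValue, grad = function(p) c(0, 0))
  }
  candidateCVSet(X, evs)
}

#' Select the physical CVs most correlated with the diffusion coordinates
#'
#' For each of the first \code{nDCs} nontrivial eigenvectors, ranks every
#' candidate CV by absolute Pearson correlation \eqn{|\rho|} (computed on
#' the stored candidate values) and chooses the best not-yet-chosen
#' candidate per eigenvector, in eigenvector order.  Equal \eqn{|\rho|}
#' is broken toward the lower candidate index.
#'
#' @param decomposition a \code{\linkS4class{SpectralDecomposition}} on
#'   the same samples as the candidate values.
#' @param candidates a \code{\linkS4class{CandidateCVSet}}.
#' @param nDCs number of diffusion coordinates to serve (>= 1).
#' @return a \code{\linkS4class{CVSelection}}.
#' @export
selectCVs <- function(decomposition, candidates, nDCs = 1L) {
  stopifnot(is(decomposition, "SpectralDecomposition"),
            is(candidates, "CandidateCVSet"), nDCs >= 1L)
  V <- decomposition@vectors
  if (ncol(V) < nDCs + 1L)
    stop("decomposition has fewer diffusion coordinates than requested")
  C <- candidates@values
  if (nrow(C) != nrow(V))
    stop("candidate values and decomposition cover different samples")
  p <- ncol(C)
  if (p < nDCs) stop("fewer distinct candidates than coordinates to serve")
  ranked <- do.call(rbind, lapply(seq_len(nDCs), function(dc) {
    phi <- V[, dc + 1L]
    rho <- vapply(seq_len(p), function(j) pearsonCorrelation(phi, C[, j]),
                  numeric(1L))
    ord <- order(-abs(rho), seq_len(p))   # ties toward lower index
    data.frame(candidate = ord, cvName = candidates@cvNames[ord],
               dc = dc, rho = rho[ord], row.names = NULL)
  }))
  chosen <- ranked[0, ]
  taken <- integer(0)
  for (dc in seq_len(nDCs)) {
    sub <- ranked[ranked$dc == dc & !(ranked$candidate %in% taken), ]
    chosen <- rbind(chosen, sub[1L, ])
    taken <- c(taken, sub$candidate[1L])
  }
  rownames(chosen) <- NULL
  new("CVSelection", ranked = ranked, chosen = chosen)
}

#' Jointly least-correlated candidate
#'
#' The candidate whose largest absolute Pearson correlation across all
#' served diffusion coordinates is smallest -- the negative control of
#' the CV selection (biasing along it should never outperform the
#' learned CVs).
#'
#' @param selection a \code{\linkS4class{CVSelection}}.
#' @return one-row data.frame with the candidate index, name and its
#'   maximal |rho|.
#' @export
leastCorrelated <- function(selection) {
  r <- selection@ranked
  agg <- stats::aggregate(abs(r$rho), by = list(candidate = r$candidate),
                          FUN = max)
  i <- agg$candidate[which.min(agg$x)]
  data.frame(candidate = i,
             cvName = r$cvName[match(i, r$candidate)],
             maxAbsRho = min(agg$x))
}

## count sign changes of a CV series, ignoring values inside a dead band
## around zero (so noise at the barrier top is not counted as crossings)
countTransitions <- function(z, deadband = 0) {
  s <- sign(z[abs(z) > deadband])
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(diff(s) != 0)
}

#' Run the adaptive CV-learning / metadynamics loop
#'
#' Reconstruction of the enhanced-sampling loop: per iteration, (1)
#' sample the current metastable state (plain overdamped Langevin by
#' default, or Fleming--Viot inside a supplied domain indicator) while
#' monitoring the diffusion-map spectrum until the window means
#' stabilize; (2) build the \eqn{\alpha = 1/2} generator on the local
#' samples and decompose it; (3) select the candidate CVs most
#' correlated with the leading diffusion coordinates; (4) run
#' metadynamics along the selected CV(s), keeping the accumulated bias
#' across iterations; (5) count transitions of the transition coordinate
#' and record a TMDmap-reweighted diagnostic (first nonzero eigenvalue
#' of the generator rebuilt on the biased samples with Boltzmann target
#' density).  The published outline of this loop is narrative only; this
#' implementation is a faithful reconstruction and is labelled as such.
#'
#' Convergence rule: the local spectrum is declared stable when the
#' relative change of the window mean eigenvalue stays below
#' \code{convTol} across \code{convWindows} consecutive windows.  If the
#' window budget is exhausted first the report is marked inconclusive
#' (not an error).
#'
#' @param config named list with entries: \code{potential}, \code{beta},
#'   \code{dt}, \code{x0}, \code{seed}; candidate CVs
#'   (\code{candidates}: named list of evaluators, or a function
#'   \code{samples -> CandidateCVSet}); local-sampling settings
#'   (\code{windowSize}, \code{subsample}, \code{maxWindows}, \code{eps},
#'   \code{k}, \code{convTol} = 0.05, \code{convWindows} = 3); selection
#'   (\code{nDCs} = 1); metadynamics (\code{hillHeight},
#'   \code{hillWidth}, \code{stride}, \code{metaSteps}); loop control
#'   (\code{nIterations}, \code{transitionCV} = first coordinate,
#'   \code{deadband} = 0, \code{domain} = NULL for Fleming--Viot,
#'   \code{nReplicas}, \code{cutoff} = 0, \code{selectionRule} =
#'   \code{"most"}; \code{"least"} biases only the jointly
#'   least-correlated candidate as a negative control).
#' @return an \code{\linkS4class{AdaptiveRunReport}}.
#' @export
runAdaptiveSampling <- function(config) {
  cfg <- config
  defaults <- list(convTol = 0.05, convWindows = 3L, nDCs = 1L,
                   deadband = 0, cutoff = 0, domain = NULL,
                   nReplicas = 50L, scheme = "euler",
                   selectionRule = "most",
                   transitionCV = function(p) p[1])
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  required <- c("potential", "beta", "dt", "x0", "seed", "candidates",
                "windowSize", "subsample", "maxWindows", "eps", "k",
                "hillHeight", "hillWidth", "stride", "metaSteps",
                "nIterations")
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    stop("config is missing: ", paste(missing, collapse = ", "))

  pot <- cfg$potential
  seeds <- list(root = as.integer(cfg$seed))
  x <- as.numeric(cfg$x0)
  biasByCV <- list()
  iterations <- list()
  transitions <- 0L
  inconclusive <- FALSE
  span <- cfg$windowSize * cfg$subsample

  for (it in seq_len(cfg$nIterations)) {
    itSeed <- deriveSeed(cfg$seed, 100L * it)
    seeds[[sprintf("iteration%d_sampling", it)]] <- itSeed

    ## (1) local sampling window by window until the spectrum stabilizes
    localPts <- NULL
    means <- numeric(0)
    evRows <- list()
    converged <- FALSE
    for (w in seq_len(cfg$maxWindows)) {
      wSeed <- deriveSeed(itSeed, w)
      if (is.null(cfg$domain)) {
        tr <- simulateOverdamped(pot, cfg$beta, cfg$dt, span, x, wSeed,
                                 scheme = cfg$scheme)
        Xw <- tr@points[-1L, , drop = FALSE]
        x <- Xw[nrow(Xw), ]
      } else {
        fv <- flemingViot(pot, cfg$beta, cfg$dt, cfg$domain,
                          cfg$nReplicas, ceiling(span / cfg$nReplicas),
                          x, wSeed, snapshotEvery = 1L)
        Xw <- do.call(rbind, fv@history)
      }
      pts <- Xw[seq.int(1L, nrow(Xw), by = cfg$subsample), , drop = FALSE]
      localPts <- rbind(localPts, pts)
      gen <- buildGenerator(buildKernel(pts, cfg$eps, cfg$cutoff),
                            alpha = 0.5)
      dec <- spectralDecompose(gen, cfg$k)
      evRows[[w]] <- dec@values[-1L]
      means <- c(means, mean(dec@values[-1L]))
      if (w >= cfg$convWindows) {
        recent <- means[seq.int(w - cfg$convWindows + 1L, w)]
        if (all(abs(diff(recent)) <= cfg$convTol * abs(recent[-1L]))) {
          converged <- TRUE
          break
        }
      }
    }
    if (!converged) inconclusive <- TRUE
    series <- flagSpectrumExit(evRows)

    ## (2) decompose the pooled local samples
    nPool <- min(nrow(localPts), 2L * cfg$windowSize)
    pool <- localPts[seq.int(1L, nrow(localPts),
                             length.out = nPool), , drop = FALSE]
    gen <- buildGenerator(buildKernel(pool, cfg$eps, cfg$cutoff),
                          alpha = 0.5)
    dec <- spectralDecompose(gen, max(cfg$k, cfg$nDCs))

    ## (3) CV selection
    cand <- if (is.function(cfg$candidates)) cfg$candidates(pool)
            else candidateCVSet(pool, cfg$candidates)
    sel <- selectCVs(dec, cand, nDCs = cfg$nDCs)

    ## (4) metadynamics along the chosen CVs, bias kept across iterations
    metaSeed <- deriveSeed(cfg$seed, 100L * it + 50L)
    seeds[[sprintf("iteration%d_metadynamics", it)]] <- metaSeed
    if (cfg$selectionRule == "least") {
      ## negative control: bias only along the jointly least-correlated
      ## candidate (same step budget as the learned-CV run)
      lc <- leastCorrelated(sel)
      sel@chosen <- sel@chosen[1L, , drop = FALSE]
      sel@chosen$candidate <- lc$candidate
      sel@chosen$cvName <- lc$cvName
      sel@chosen$rho <- lc$maxAbsRho
    }
    chosenNames <- sel@chosen$cvName
    nHills <- 0L
    metaTraj <- NULL
    perCV <- max(1L, floor(cfg$metaSteps / length(chosenNames)))
    for (ci in seq_along(chosenNames)) {
      nm <- chosenNames[ci]
      cv <- cand@evaluators[[sel@chosen$candidate[ci]]]
      res <- simulateMetadynamics(pot, cv, cfg$beta, cfg$dt, perCV,
                                  cfg$hillHeight, cfg$hillWidth,
                                  cfg$stride, x,
                                  deriveSeed(metaSeed, ci),
                                  scheme = cfg$scheme,
                                  bias = biasByCV[[nm]])
      biasByCV[[nm]] <- res$bias
      nHills <- nHills + length(res$bias@centers)
      metaTraj <- rbind(metaTraj, res$trajectory@points[-1L, , drop = FALSE])
      x <- metaTraj[nrow(metaTraj), ]
    }
    zTrans <- apply(metaTraj, 1L, cfg$transitionCV)
    itTrans <- countTransitions(zTrans, cfg$deadband)
    transitions <- transitions + itTrans

    ## (5) TMDmap-reweighted diagnostic on the biased samples: target is
    ## the unbiased Boltzmann density, so the first nonzero eigenvalue
    ## estimates the unbiased relaxation rate
    diagEig <- NA_real_
    diagPts <- metaTraj[seq.int(1L, nrow(metaTraj),
                                length.out = min(nrow(metaTraj),
                                                 cfg$windowSize)), ,
                        drop = FALSE]
    diagEig <- tryCatch({
      tgt <- exp(-cfg$beta * energyAt(pot, diagPts))
      ker <- buildKernel(diagPts, cfg$eps, cfg$cutoff)
      tmd <- buildTMDmap(ker, targetDensity = tgt)
      spectralDecompose(tmd, 1L)@values[2L]
    }, error = function(e) NA_real_)

    iterations[[it]] <- list(
      windows = length(means), spectrumSeries = series,
      spectrumConverged = converged, selection = sel,
      chosen = chosenNames, nHills = nHills,
      transitions = itTrans, tmdmapEigenvalue = diagEig,
      finalPosition = x)
  }

  new("AdaptiveRunReport", iterations = iterations, seeds = seeds,
      config = cfg, transitions = as.integer(transitions),
      inconclusive = inconclusive)
}
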