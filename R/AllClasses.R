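#' @import methods
#' @importFrom Matrix rowSums Diagonal sparseMatrix t crossprod
#' @importClassesFrom Matrix Matrix
#' @importFrom stats rnorm runif sd cor setNames
NULL

setClassUnion("matrixOrSparse", c("matrix", "Matrix"))

#' Potential energy surface
#'
#' An analytic potential \eqn{V(x)} on \eqn{R^d} together with its exact
#' gradient.  Instances are created by the constructors
#' \code{\link{quadraticPotential}}, \code{\link{doubleWell1D}},
#' \code{\link{shiftedDoubleWell1D}}, \code{\link{doubleWell2D}} and
#' \code{\link{flatPotential}}, or directly with \code{makePotential}.
#'
#' @slot name identifier of the potential.
#' @slot params named list of real parameters (e.g. \code{h}, \code{w} for
#'   the two-dimensional double well).
#' @slot dimension dimension \eqn{d} of configuration space.
#' @slot energy function mapping a length-\eqn{d} numeric to the energy.
#' @slot gradient function mapping a length-\eqn{d} numeric to the exact
#'   analytic gradient.
#' @export
setClass("Potential",
  slots = c(name = "character", params = "list", dimension = "integer",
            energy = "function", gradient = "function"),
  validity = function(object) {
    if (length(object@dimension) != 1L || object@dimension < 1L)
      return("dimension must be a single positive integer")
    TRUE
  })

#' Simulated trajectory
#'
#' Output of the stochastic integrators: an ordered sample of
#' configurations together with the integration parameters needed to
#' reproduce it bit-for-bit.
#'
#' @slot points m x d matrix of configurations (row 1 is the initial
#'   condition).
#' @slot dt integration time step.
#' @slot beta inverse temperature.
#' @slot seed integer seed of the noise stream.
#' @slot scheme integrator identifier, \code{"euler"} (Euler--Maruyama) or
#'   \code{"lm"} (Leimkuhler--Matthews postprocessed step).
#' @export
setClass("Trajectory",
  slots = c(points = "matrix", dt = "numeric", beta = "numeric",
            seed = "integer", scheme = "character"),
  validity = function(object) {
    if (nrow(object@points) < 1L) return("trajectory must contain >= 1 row")
    if (!all(is.finite(object@points))) return("non-finite trajectory entries")
    if (object@dt <= 0) return("dt must be positive")
    if (object@beta <= 0) return("beta must be positive")
    TRUE
  })

#' Metadynamics bias state
#'
#' Accumulated Gaussian hills along a scalar collective variable.  The
#' bias value at CV value \eqn{z} is
#' \deqn{V_b(z) = \sum_k h \exp(-(z - z_k)^2 / (2 w^2)),}
#' with deposition height \eqn{h}, width \eqn{w} and hill centres
#' \eqn{z_k}.
#'
#' @slot centers numeric vector of deposited hill centres (CV values).
#' @slot height hill height (energy units).
#' @slot width hill width (CV units).
#' @slot stride deposition stride in integrator steps.
#' @export
setClass("BiasState",
  slots = c(centers = "numeric", height = "numeric", width = "numeric",
            stride = "integer"),
  validity = function(object) {
    if (object@width <= 0) return("hill width must be positive")
    if (object@stride < 1L) return("stride must be >= 1")
    TRUE
  })

#' Fleming-Viot replica ensemble
#'
#' Final state of a Fleming--Viot particle process: replicas evolving by
#' overdamped Langevin dynamics inside a domain, with any replica leaving
#' the domain restarted from the position of a uniformly chosen surviving
#' replica.  The empirical law of the ensemble approximates the
#' quasi-stationary distribution of the domain.
#'
#' @slot positions n x d matrix of replica positions (all inside the
#'   domain).
#' @slot nKills number of kill/restart events during the run.
#' @slot domain predicate function: configuration -> logical, defining the
#'   domain.
#' @slot history optional list of pooled position snapshots.
#' @export
setClass("ReplicaEnsemble",
  slots = c(positions = "matrix", nKills = "integer", domain = "function",
            history = "list"))

#' Point cloud of configurations
#'
#' The basic data container: \eqn{m} sampled configurations in \eqn{d}
#' dimensions with optional per-point weights (e.g. target-density values
#' or importance-sampling reweighting factors) and free-form provenance
#' metadata.
#'
#' @slot points m x d numeric matrix, one configuration per row.
#' @slot weights numeric of length 0 (absent) or m, strictly positive.
#' @slot metadata named list of provenance (potential, beta, dt, seed, ...).
#' @export
setClass("PointCloud",
  slots = c(points = "matrix", weights = "numeric", metadata = "list"),
  validity = function(object) {
    if (nrow(object@points) < 2L) return("a point cloud needs >= 2 points")
    if (!all(is.finite(object@points))) return("non-finite coordinates")
    if (length(object@weights) &&
        length(object@weights) != nrow(object@points))
      return("weights must have one entry per point")
    if (length(object@weights) && any(object@weights <= 0))
      return("weights must be strictly positive")
    TRUE
  })

#' Gaussian kernel matrix
#'
#' Symmetric kernel matrix \eqn{K_{ij} = \exp(-\|x_i-x_j\|^2/(4\epsilon))}
#' evaluated on a point cloud; entries below \code{cutoff} are stored as
#' exact zeros (sparse storage).
#'
#' @slot values m x m symmetric non-negative matrix (dense or
#'   \code{Matrix} sparse).
#' @slot epsilon kernel bandwidth \eqn{\epsilon > 0}.
#' @slot cutoff sparsification threshold (0 = dense).
#' @export
setClass("KernelMatrix",
  slots = c(values = "matrixOrSparse", epsilon = "numeric",
            cutoff = "numeric"),
  validity = function(object) {
    if (object@epsilon <= 0) return("epsilon must be positive")
    if (object@cutoff < 0) return("cutoff must be >= 0")
    TRUE
  })

#' Generator matrix approximation
#'
#' The \eqn{\epsilon}-scaled normalized-graph-Laplacian approximation
#' \eqn{L_\epsilon = \epsilon^{-1}(P_\epsilon - I)} of the generator of
#' overdamped Langevin dynamics (kind \code{"alpha_normalized"}), or the
#' target-measure variant (kind \code{"tmdmap"}).  Rows sum to zero and
#' off-diagonal entries are non-negative, so \eqn{P_\epsilon = I +
#' \epsilon L_\epsilon} is a row-stochastic Markov matrix.
#'
#' @slot values m x m generator matrix.
#' @slot epsilon kernel bandwidth used in the construction.
#' @slot alpha density-normalization exponent in [0,1] (ignored for
#'   TMDmap).
#' @slot kind \code{"alpha_normalized"} or \code{"tmdmap"}.
#' @slot q kernel density estimate (row sums of the kernel matrix).
#' @slot stationaryWeight positive vector \eqn{\mu} with
#'   \eqn{\mathrm{diag}(\mu)P_\epsilon} symmetric; used to symmetrize
#'   eigenproblems.
#' @export
setClass("GeneratorMatrix",
  slots = c(values = "matrixOrSparse", epsilon = "numeric", alpha = "numeric",
            kind = "character", q = "numeric", stationaryWeight = "numeric"),
  validity = function(object) {
    if (!object@kind %in% c("alpha_normalized", "tmdmap"))
      return("kind must be 'alpha_normalized' or 'tmdmap'")
    if (object@kind == "alpha_normalized" &&
        (object@alpha < 0 || object@alpha > 1))
      return("alpha must lie in [0, 1]")
    TRUE
  })

#' Spectral decomposition of a generator matrix
#'
#' Dominant eigenpairs of a \code{\linkS4class{GeneratorMatrix}}:
#' eigenvalues \eqn{0 = \lambda_0 > \lambda_1 \ge \ldots} sorted
#' decreasingly, eigenvectors with unit 2-norm and sign fixed so the
#' largest-magnitude entry is positive.  Columns beyond the first are the
#' diffusion coordinates.
#'
#' @slot values numeric vector of k+1 eigenvalues, decreasing, values[1]
#'   = 0 within tolerance.
#' @slot vectors m x (k+1) matrix of eigenvectors (column j+1 is
#'   \eqn{\phi_j}).
#' @slot epsilon bandwidth of the generator that was decomposed.
#' @slot residuals per-pair residual norms \eqn{\|Lv-\lambda v\|}.
#' @export
setClass("SpectralDecomposition",
  slots = c(values = "numeric", vectors = "matrix", epsilon = "numeric",
            residuals = "numeric"))

#' Committor field on a point cloud
#'
#' Per-point committor values \eqn{q(x_i)}: the probability of reaching
#' set B before set A from \eqn{x_i}.  Values are exactly 0 on A and 1 on
#' B; values outside \eqn{[-0.05, 1.05]} are flagged (never silently
#' clamped).
#'
#' @slot values numeric committor values, one per point.
#' @slot idxA,idxB disjoint integer index sets defining A and B.
#' @slot flagged logical per point: TRUE where the value leaves
#'   \eqn{[-0.05, 1.05]}.
#' @export
setClass("CommittorField",
  slots = c(values = "numeric", idxA = "integer", idxB = "integer",
            flagged = "logical"),
  validity = function(object) {
    if (length(intersect(object@idxA, object@idxB)))
      return("idxA and idxB must be disjoint")
    if (any(object@values[object@idxA] != 0)) return("values must be 0 on A")
    if (any(object@values[object@idxB] != 1)) return("values must be 1 on B")
    TRUE
  })

#' Dirichlet spectrum on a point-cloud subdomain
#'
#' Eigenpairs of the principal submatrix \eqn{L_\epsilon[\Omega,\Omega]}
#' of a generator matrix, i.e. the point-cloud realization of the
#' generator with homogeneous Dirichlet conditions outside \eqn{\Omega}.
#' Eigenvectors are embedded back into the full cloud with exact zeros
#' outside the domain.
#'
#' @slot eigenvalues negative reals, sorted decreasingly.
#' @slot eigenvectors m x k matrix, zero outside the domain.
#' @slot domainIdx integer indices of the points in \eqn{\Omega}.
#' @export
setClass("DirichletSpectrum",
  slots = c(eigenvalues = "numeric", eigenvectors = "matrix",
            domainIdx = "integer"))

#' Quasi-stationary distribution on a 1D grid
#'
#' First Dirichlet eigenpair of the (time-rescaled) generator
#' \eqn{L = -\beta V' \partial + \partial^2} on an interval, solved
#' pseudo-spectrally on Chebyshev--Gauss--Lobatto nodes.  \code{v} is the
#' first eigenfunction normalized to unit mean against the Boltzmann
#' measure restricted to the interval; \code{nu} is the QSD density
#' \eqn{\nu \propto v e^{-\beta V}} normalized to unit integral.
#'
#' @slot grid Chebyshev nodes (decreasing, includes endpoints).
#' @slot v first Dirichlet eigenfunction on the grid.
#' @slot nu QSD density on the grid.
#' @slot lambda1 first exit rate \eqn{\lambda > 0} (eigenvalue is
#'   \eqn{-\lambda}).
#' @slot interval domain \eqn{[a, b]}.
#' @slot quadWeights Clenshaw--Curtis quadrature weights on the grid.
#' @slot converged FALSE when doubling the grid moved the first eigenvalue
#'   by more than 1e-6.
#' @export
setClass("QSDResult",
  slots = c(grid = "numeric", v = "numeric", nu = "numeric",
            lambda1 = "numeric", interval = "numeric",
            quadWeights = "numeric", converged = "logical"))

#' Two-set metastable partition
#'
#' Metastable sets identified from the sign structure of the first
#' diffusion coordinate: centres at the argmax/argmin of \eqn{\phi_1},
#' each set grown to the points within a diffusion-distance threshold of
#' its centre.
#'
#' @slot centerMax,centerMin indices of the argmax / argmin of
#'   \eqn{\phi_1}.
#' @slot membersA,membersB disjoint member index sets (A contains
#'   centerMax).
#' @slot threshold growth radius in diffusion space.
#' @slot embeddingDim number of diffusion coordinates used for the
#'   distance.
#' @export
setClass("MetastablePartition",
  slots = c(centerMax = "integer", centerMin = "integer",
            membersA = "integer", membersB = "integer",
            threshold = "numeric", embeddingDim = "integer"),
  validity = function(object) {
    if (!(object@centerMax %in% object@membersA))
      return("centerMax must belong to membersA")
    if (!(object@centerMin %in% object@membersB))
      return("centerMin must belong to membersB")
    if (length(intersect(object@membersA, object@membersB)))
      return("membersA and membersB must be disjoint")
    TRUE
  })

#' Windowed diffusion-map spectrum series
#'
#' Dominant generator eigenvalues recomputed on successive trajectory
#' windows, with the per-window mean and maximal successive difference,
#' and the first window (if any) at which the mean jumps by more than
#' \code{jumpFactor} trailing standard deviations -- the exit detector.
#'
#' @slot steps window start step indices.
#' @slot eigenvalues W x k matrix, row w = dominant nonzero eigenvalues of
#'   window w.
#' @slot means per-window mean eigenvalue.
#' @slot maxdiffs per-window maximal successive eigenvalue difference.
#' @slot exitFlag index of the first flagged window, or NA.
#' @slot jumpFactor detection multiplier used.
#' @export
setClass("SpectrumWindowSeries",
  slots = c(steps = "integer", eigenvalues = "matrix", means = "numeric",
            maxdiffs = "numeric", exitFlag = "integer",
            jumpFactor = "numeric"),
  validity = function(object) {
    if (length(object@means) != nrow(object@eigenvalues) ||
        length(object@maxdiffs) != nrow(object@eigenvalues))
      return("means/maxdiffs lengths must match the number of windows")
    TRUE
  })

#' Candidate collective-variable set
#'
#' Physically interpretable candidate CVs evaluated along a sample, kept
#' together with their evaluator functions for on-the-fly use during
#' biased dynamics.
#'
#' @slot cvNames candidate identifiers.
#' @slot values m x p matrix, column j = candidate j along the samples.
#' @slot evaluators list of functions configuration -> scalar reproducing
#'   the stored columns on the stored samples.
#' @export
setClass("CandidateCVSet",
  slots = c(cvNames = "character", values = "matrix", evaluators = "list"),
  validity = function(object) {
    if (ncol(object@values) != length(object@cvNames))
      return("column count must equal name count")
    if (length(object@evaluators) != length(object@cvNames))
      return("one evaluator per candidate required")
    TRUE
  })

#' Collective-variable selection
#'
#' Ranking of candidate CVs by absolute Pearson correlation against the
#' leading diffusion coordinates, and the chosen (best distinct) candidate
#' per coordinate.
#'
#' @slot ranked data.frame(candidate, cvName, dc, rho) sorted within each
#'   dc by decreasing |rho|.
#' @slot chosen data.frame with one row per requested diffusion
#'   coordinate.
#' @export
setClass("CVSelection",
  slots = c(ranked = "data.frame", chosen = "data.frame"))

#' Adaptive sampling run report
#'
#' Full record of an adaptive CV-learning / metadynamics run: one entry
#' per iteration (local-sampling spectrum series, CV selection,
#' metadynamics summary, transition count) plus the complete seed ledger
#' from which the run can be reproduced.
#'
#' @slot iterations list of per-iteration records.
#' @slot seeds named list of every derived seed.
#' @slot config the input configuration.
#' @slot transitions total transition count across the run.
#' @slot inconclusive TRUE when the local spectrum never stabilized within
#'   the window budget.
#' @export
setClass("AdaptiveRunReport",
  slots = c(iterations = "list", seeds = "list", config = "list",
            transitions = "integer", inconclusive = "logical"))
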