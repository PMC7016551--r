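#' Derive a reproducible sub-stream seed
#'
#' One root seed spawns per-replica / per-trajectory sub-seeds through the
#' fixed affine rule \code{(root * 7919 + k) mod (2^31 - 1) + 1}, keeping
#' every derived seed a valid positive 32-bit integer.  All stochastic
#' operations in the package derive their internal streams this way, so a
#' run is bit-reproducible from its root seed.
#'
#' @param root integer root seed.
#' @param k non-negative stream index.
#' @return integer sub-seed.
#' @export
deriveSeed <- function(root, k) {
  as.integer((as.double(root) * 7919 + k) %% 2147483646) + 1L
}

## Pre-generated standard-normal increments: (n_steps + 1) x d, so the
## Leimkuhler-Matthews step can average consecutive rows.
noiseMatrix <- function(seed, nSteps, d) {
  set.seed(seed)
  matrix(rnorm((nSteps + 1L) * d), nrow = nSteps + 1L, ncol = d)
}

#' Simulate overdamped Langevin dynamics
#'
#' Integrates \eqn{dx_t = -\nabla V(x_t)\,dt + \sqrt{2/\beta}\,dW_t}
#' from \code{x0}.  Two schemes are provided: plain Euler--Maruyama
#' (\code{"euler"}),
#' \deqn{x_{n+1} = x_n - \nabla V(x_n)\Delta t + \sqrt{2\Delta t/\beta}\,\xi_n,}
#' and the Leimkuhler--Matthews postprocessed step (\code{"lm"}), which
#' replaces \eqn{\xi_n} by \eqn{(\xi_n + \xi_{n+1})/2} and samples the
#' configurational Boltzmann measure with higher-order accuracy (it is
#' exact for the stationary variance of the quadratic well).
#'
#' @param potential a \code{\linkS4class{Potential}}.
#' @param beta inverse temperature (> 0).
#' @param dt time step (> 0).
#' @param nSteps number of steps; the trajectory has \code{nSteps + 1}
#'   rows starting at \code{x0}.
#' @param x0 initial configuration.
#' @param seed integer seed; identical seeds give bit-identical
#'   trajectories.
#' @param scheme \code{"euler"} or \code{"lm"}.
#' @param noiseScale multiplier on the noise amplitude; 0 gives the
#'   deterministic gradient flow (useful for checks).
#' @return a \code{\linkS4class{Trajectory}}.
#' @examples
#' tr <- simulateOverdamped(quadraticPotential(), beta = 1, dt = 0.01,
#'                          nSteps = 100, x0 = 1, seed = 1)
#' nPoints(tr)
#' @export
simulateOverdamped <- function(potential, beta, dt, nSteps, x0, seed,
                               scheme = c("euler", "lm"), noiseScale = 1) {
  scheme <- match.arg(scheme)
  stopifnot(dt > 0, beta > 0, nSteps >= 0)
  x0 <- as.numeric(x0)
  if (length(x0) != potential@dimension)
    stop("x0 has the wrong dimension for this potential")
  d <- potential@dimension
  out <- matrix(NA_real_, nrow = nSteps + 1L, ncol = d)
  out[1L, ] <- x0
  if (nSteps > 0L) {
    G <- noiseMatrix(seed, nSteps, d)
    amp <- noiseScale * sqrt(2 * dt / beta)
    grad <- potential@gradient
    x <- x0
    for (n in seq_len(nSteps)) {
      xi <- if (scheme == "lm") (G[n, ] + G[n + 1L, ]) / 2 else G[n, ]
      x <- x - grad(x) * dt + amp * xi
      if (!all(is.finite(x)))
        stop(sprintf("trajectory diverged (non-finite state) at step %d", n))
      out[n + 1L, ] <- x
    }
  }
  new("Trajectory", points = out, dt = dt, beta = beta,
      seed = as.integer(seed), scheme = scheme)
}

#' Evaluate a metadynamics bias and its derivative
#'
#' The bias is a sum of Gaussian hills along the collective variable:
#' \eqn{V_b(z) = \sum_k h \exp(-(z - z_k)^2/(2 w^2))}.
#'
#' @param bias a \code{\linkS4class{BiasState}}.
#' @param z CV value(s) at which to evaluate.
#' @return list with \code{value} and \code{derivative} (same length as
#'   \code{z}); both zero when no hills have been deposited.
#' @export
evaluateBias <- function(bias, z) {
  stopifnot(is(bias, "BiasState"))
  if (!length(bias@centers))
    return(list(value = numeric(length(z)),
                derivative = numeric(length(z))))
  dz <- outer(z, bias@centers, "-")
  e <- bias@height * exp(-dz^2 / (2 * bias@width^2))
  list(value = rowSums(e),
       derivative = rowSums(-dz / bias@width^2 * e))
}

## Normalize a CV specification to list(value=function, grad=function).
## A bare function gets a central finite-difference gradient.
asCV <- function(cv, d) {
  if (is.list(cv) && is.function(cv$value) && is.function(cv$grad))
    return(cv)
  if (is.function(cv)) {
    f <- cv
    return(list(value = f, grad = function(x) {
      h <- 1e-6
      vapply(seq_len(d), function(i) {
        e <- numeric(d); e[i] <- h
        (f(x + e) - f(x - e)) / (2 * h)
      }, numeric(1L))
    }))
  }
  stop("cv must be a function or a list(value=, grad=)")
}

#' Simulate metadynamics-biased overdamped Langevin dynamics
#'
#' Runs overdamped Langevin dynamics under the force
#' \eqn{-\nabla V - V_b'(\mathrm{cv}(x))\,\nabla \mathrm{cv}(x)},
#' depositing one Gaussian hill at the current CV value every
#' \code{stride} steps.  With \code{hillHeight = 0} the trajectory is
#' bit-identical to \code{\link{simulateOverdamped}} at the same seed.
#' The bias is standard (non-well-tempered) metadynamics; height, width
#' and stride are required with no silent defaults.
#'
#' @param potential,beta,dt,nSteps,x0,seed,scheme as in
#'   \code{\link{simulateOverdamped}}.
#' @param cv scalar collective variable: a function of the configuration,
#'   or a list \code{list(value=, grad=)} with the exact gradient.
#' @param hillHeight,hillWidth,stride Gaussian-hill parameters.
#' @param bias optional \code{\linkS4class{BiasState}} to continue from
#'   (accumulated bias is kept across adaptive iterations).
#' @return list with elements \code{trajectory}
#'   (\code{\linkS4class{Trajectory}}) and \code{bias}
#'   (\code{\linkS4class{BiasState}} with the newly deposited hills
#'   appended).
#' @export
simulateMetadynamics <- function(potential, cv, beta, dt, nSteps,
                                 hillHeight, hillWidth, stride, x0, seed,
                                 scheme = c("euler", "lm"), bias = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(dt > 0, beta > 0, stride >= 1, hillWidth > 0)
  d <- potential@dimension
  x0 <- as.numeric(x0)
  if (length(x0) != d) stop("x0 has the wrong dimension for this potential")
  cv <- asCV(cv, d)
  centers <- if (is.null(bias)) numeric(0) else bias@centers
  out <- matrix(NA_real_, nrow = nSteps + 1L, ncol = d)
  out[1L, ] <- x0
  if (nSteps > 0L) {
    G <- noiseMatrix(seed, nSteps, d)
    amp <- sqrt(2 * dt / beta)
    grad <- potential@gradient
    x <- x0
    w2 <- hillWidth^2
    for (n in seq_len(nSteps)) {
      force <- -grad(x)
      if (hillHeight != 0 && length(centers)) {
        g <- cv$grad(x)
        if (any(g != 0)) {          # zero-gradient CVs exert no force
          z <- cv$value(x)
          dz <- z - centers
          dVb <- sum(-dz / w2 * hillHeight * exp(-dz^2 / (2 * w2)))
          force <- force - dVb * g
        }
      }
      xi <- if (scheme == "lm") (G[n, ] + G[n + 1L, ]) / 2 else G[n, ]
      x <- x + force * dt + amp * xi
      if (!all(is.finite(x)))
        stop(sprintf("trajectory diverged (non-finite state) at step %d", n))
      out[n + 1L, ] <- x
      if (n %% stride == 0L) centers <- c(centers, cv$value(x))
    }
  }
  list(trajectory = new("Trajectory", points = out, dt = dt, beta = beta,
                        seed = as.integer(seed), scheme = scheme),
       bias = new("BiasState", centers = centers, height = hillHeight,
                  width = hillWidth, stride = as.integer(stride)))
}

#' Fleming-Viot particle process
#'
#' Evolves \code{nReplicas} replicas by Euler--Maruyama overdamped
#' Langevin dynamics inside the domain defined by \code{domain}.  After
#' each full step, replicas violating the domain indicator are processed
#' in replica-index order and each is restarted at the position of a
#' uniformly chosen replica currently inside the domain.  The stationary
#' empirical law of the ensemble approximates the quasi-stationary
#' distribution of the domain.  Replica \code{j} uses the noise stream of
#' \code{deriveSeed(seed, j)}; with an always-true indicator the replicas
#' are exactly \code{nReplicas} independent unbiased trajectories.
#'
#' The kill/restart bookkeeping follows the standard Fleming--Viot
#' construction (the source narrative leaves its boundary details to a
#' footnote; this reconstruction is the classical one).
#'
#' @param potential,beta,dt,seed as in \code{\link{simulateOverdamped}}.
#' @param domain predicate: configuration (numeric vector) -> logical;
#'   \code{x0} must satisfy it.
#' @param nReplicas number of replicas (>= 2).
#' @param nSteps number of steps.
#' @param x0 common initial configuration.
#' @param snapshotEvery if > 0, pool replica positions every this many
#'   steps into the \code{history} slot (for density estimates).
#' @return a \code{\linkS4class{ReplicaEnsemble}}.
#' @export
flemingViot <- function(potential, beta, dt, domain, nReplicas, nSteps,
                        x0, seed, snapshotEvery = 0L) {
  stopifnot(dt > 0, beta > 0, nReplicas >= 2)
  x0 <- as.numeric(x0)
  d <- potential@dimension
  if (length(x0) != d) stop("x0 has the wrong dimension for this potential")
  if (!isTRUE(domain(x0))) stop("x0 must satisfy the domain indicator")
  ## per-replica noise streams, pre-generated so the kill stream (the
  ## only on-demand randomness) can own the global RNG during the loop
  noise <- lapply(seq_len(nReplicas),
                  function(j) noiseMatrix(deriveSeed(seed, j), nSteps, d))
  set.seed(deriveSeed(seed, 0L))
  X <- matrix(rep(x0, each = nReplicas), nrow = nReplicas, ncol = d)
  amp <- sqrt(2 * dt / beta)
  nKills <- 0L
  history <- list()
  inside <- rep(TRUE, nReplicas)
  for (n in seq_len(nSteps)) {
    Gn <- matrix(vapply(noise, function(G) G[n, ], numeric(d)), nrow = d)
    X <- X - gradientAt(potential, X) * dt + amp * t(Gn)
    for (j in seq_len(nReplicas))
      inside[j] <- isTRUE(domain(X[j, ]))
    if (!any(inside))
      stop(sprintf(
        "all replicas left the domain at step %d (domain too small or dt too large)",
        n))
    if (!all(inside)) {
      for (j in which(!inside)) {
        survivors <- which(inside)
        pick <- survivors[floor(runif(1L) * length(survivors)) + 1L]
        X[j, ] <- X[pick, ]
        inside[j] <- TRUE
        nKills <- nKills + 1L
      }
    }
    if (snapshotEvery > 0L && n %% snapshotEvery == 0L)
      history[[length(history) + 1L]] <- X
  }
  new("ReplicaEnsemble", positions = X, nKills = nKills, domain = domain,
      history = history)
}

#' Subsample a trajectory into a point cloud
#'
#' Uniform-stride subsampling of a trajectory (optionally after a
#' burn-in), carrying the integration parameters along as metadata.
#'
#' @param trajectory a \code{\linkS4class{Trajectory}}.
#' @param m number of points to keep.
#' @param burnin number of leading rows to drop first.
#' @return a \code{\linkS4class{PointCloud}}.
#' @export
subsampleCloud <- function(trajectory, m, burnin = 0L) {
  X <- trajectory@points
  if (burnin > 0L) X <- X[-seq_len(burnin), , drop = FALSE]
  if (m > nrow(X)) stop("fewer rows available than requested")
  idx <- unique(round(seq(1L, nrow(X), length.out = m)))
  new("PointCloud", points = X[idx, , drop = FALSE], weights = numeric(0),
      metadata = list(dt = trajectory@dt, beta = trajectory@beta,
                      seed = trajectory@seed, scheme = trajectory@scheme))
}
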