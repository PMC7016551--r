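test_that("Pearson correlation matches hand-computed values", {
  x <- c(0, 1, 2); y <- c(1, 0, 2)
  expect_equal(pearsonCorrelation(x, y), 0.5)
  expect_equal(pearsonCorrelation(x, x), 1)
  expect_equal(pearsonCorrelation(x, -x), -1)
  expect_error(pearsonCorrelation(c(1, 1, 1), y), "zero variance")
  expect_error(pearsonCorrelation(x, c(2, 2, 2)), "zero variance")
})

test_that("candidate sets reproduce their stored values through evaluators", {
  X <- coords(trappedCloud())
  cand <- toyCandidateCVs(X, seed = 1)
  for (j in seq_along(cand@cvNames)) {
    vals <- apply(X, 1, cand@evaluators[[j]]$value)
    expect_equal(vals, cand@values[, j])
  }
})

test_that("CV selection ranks by |rho| with documented tie-breaking", {
  dec <- trappedDecomp()
  X <- coords(trappedCloud())
  phi1 <- dec@vectors[, 2]
  # a candidate equal to phi1 itself must win with |rho| = 1
  evs <- list(a = function(p) p[1], phi = local({
    lookup <- phi1; ref <- X
    function(p) lookup[which.min(colSums((t(ref) - p)^2))]
  }), b = function(p) p[2])
  cand <- candidateCVSet(X, evs)
  sel <- selectCVs(dec, cand, nDCs = 1)
  expect_identical(sel@chosen$cvName, "phi")
  expect_equal(abs(sel@chosen$rho), 1, tolerance = 1e-8)

  # duplicated candidates tie exactly; the lower index wins
  cand2 <- candidateCVSet(X, list(y1 = function(p) p[2],
                                  y2 = function(p) p[2]))
  sel2 <- selectCVs(dec, cand2, nDCs = 1)
  expect_identical(sel2@chosen$candidate, 1L)
})

test_that("an independent noise candidate decorrelates from every DC", {
  dec <- trappedDecomp()
  cand <- toyCandidateCVs(coords(trappedCloud()), seed = 1)
  sel <- selectCVs(dec, cand, nDCs = 2)
  rhoNoise <- abs(sel@ranked$rho[sel@ranked$cvName == "noise"])
  expect_true(all(rhoNoise < 0.1))
  lc <- leastCorrelated(sel)
  expect_identical(lc$cvName, "noise")
})

test_that("the trapped state selects the transverse coordinate for DC1 and x for DC2", {
  dec <- trappedDecomp()
  cand <- toyCandidateCVs(coords(trappedCloud()), seed = 1)
  sel <- selectCVs(dec, cand, nDCs = 2)
  expect_identical(sel@chosen$cvName, c("y", "x"))
  expect_gt(abs(sel@chosen$rho[1]), 0.95)
  expect_gt(abs(sel@chosen$rho[2]), 0.95)
})

test_that("zero hill height reduces the adaptive loop to plain sampling", {
  cfg <- list(potential = doubleWell2D(), beta = 10, dt = 0.02,
              x0 = c(1, 0), seed = 1,
              candidates = function(p) toyCandidateCVs(p, seed = 1),
              windowSize = 300, subsample = 4, maxWindows = 6, eps = 0.1,
              k = 3, nDCs = 1, hillHeight = 0, hillWidth = 0.25,
              stride = 250, metaSteps = 8000, nIterations = 1,
              deadband = 0.3, scheme = "lm")
  rep <- runAdaptiveSampling(cfg)
  expect_identical(rep@transitions, 0L)
  expect_false(rep@inconclusive)
})

test_that("adaptive reports are bit-reproducible from their seeds", {
  cfg <- list(potential = doubleWell2D(), beta = 10, dt = 0.02,
              x0 = c(1, 0), seed = 4,
              candidates = function(p) toyCandidateCVs(p, seed = 4),
              windowSize = 300, subsample = 4, maxWindows = 6, eps = 0.1,
              k = 3, nDCs = 2, hillHeight = 0.125, hillWidth = 0.25,
              stride = 250, metaSteps = 10000, nIterations = 1,
              deadband = 0.3, scheme = "lm")
  r1 <- runAdaptiveSampling(cfg)
  r2 <- runAdaptiveSampling(cfg)
  expect_identical(r1@seeds, r2@seeds)
  expect_identical(r1@transitions, r2@transitions)
  expect_identical(r1@iterations[[1]]$chosen, r2@iterations[[1]]$chosen)
  expect_identical(r1@iterations[[1]]$finalPosition,
                   r2@iterations[[1]]$finalPosition)
})

test_that("TMDmap reweighting of biased samples recovers the unbiased rate", {
  # metadynamics-biased 1D double-well samples, TMDmap target = unbiased
  # Boltzmann density: the first nonzero eigenvalue must match the
  # unbiased interwell rate
  pot <- doubleWell1D()
  cvx <- list(value = function(p) p[1], grad = function(p) 1)
  res <- simulateMetadynamics(pot, cvx, beta = 2, dt = 0.02, nSteps = 6e4,
                              hillHeight = 0.08, hillWidth = 0.3,
                              stride = 200, x0 = 1, seed = 8,
                              scheme = "lm")
  X <- coords(res$trajectory)
  # importance reweighting needs overlap with the target: keep the biased
  # samples inside the region where e^{-beta V} is not negligible
  X <- X[abs(X[, 1]) < 1.7, , drop = FALSE]
  idx <- round(seq(2000, nrow(X), length.out = 2000))
  Xs <- X[idx, , drop = FALSE]
  ker <- buildKernel(Xs, 0.01)
  tmd <- buildTMDmap(ker, targetDensity = exp(-2 * (Xs[, 1]^2 - 1)^2))
  lam1 <- spectralDecompose(tmd, 1)@values[2]
  # reference: the interwell relaxation rate, i.e. the eigenvalue above
  # the (numerically zero) exit mode of the large-domain Dirichlet solve
  ref <- chebyshevDirichlet(pot, 2, c(-2.2, 2.2), n = 256, k = 2,
                            checkConvergence = FALSE)$values[2]
  expect_lt(abs(lam1 - ref) / abs(ref), 0.2)
})
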