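test_that("committor boundary values are exact and flags are honest", {
  cl <- makeFixture("ou_1d", seed = 3, m = 500)
  X <- coords(cl)[, 1]
  gen <- buildGenerator(buildKernel(cl, 0.05), alpha = 0.5)
  idxA <- which(X < -1)
  idxB <- which(X > 1)
  com <- solveCommittor(gen, idxA, idxB)
  q <- committorValues(com)
  expect_true(all(q[idxA] == 0))
  expect_true(all(q[idxB] == 1))
  expect_identical(com@flagged, q < -0.05 | q > 1.05)
  expect_lt(sum(com@flagged), 5)     # approximate maximum principle
})

test_that("a symmetric 3-point chain has committor exactly one half", {
  # equally spaced points: the middle row of P gives equal weight to both
  # neighbours, so the single unknown solves to 1/2 exactly
  X <- matrix(c(-1, 0, 1), ncol = 1)
  gen <- buildGenerator(buildKernel(X, 0.5), alpha = 0)
  com <- solveCommittor(gen, idxA = 1L, idxB = 3L)
  expect_equal(committorValues(com), c(0, 0.5, 1))
})

test_that("degenerate committor set specifications error out", {
  X <- matrix(seq(-1, 1, length.out = 10), ncol = 1)
  gen <- buildGenerator(buildKernel(X, 0.2), alpha = 0.5)
  expect_error(solveCommittor(gen, integer(0), 2L), "non-empty")
  expect_error(solveCommittor(gen, 1:2, 2:3), "disjoint")
  expect_error(solveCommittor(gen, 1:5, 6:10), "non-empty")
})

test_that("Dirichlet eigenpairs are negative and vanish outside the domain", {
  cl <- makeFixture("ou_1d", seed = 4, m = 600)
  X <- coords(cl)[, 1]
  gen <- buildGenerator(buildKernel(cl, 0.02), alpha = 0.5)
  dom <- which(abs(X) < 1)
  ds <- solveDirichletEigen(gen, dom, 3)
  expect_true(all(ds@eigenvalues < 0))
  expect_true(all(diff(ds@eigenvalues) <= 0))
  outside <- setdiff(seq_along(X), dom)
  expect_true(all(ds@eigenvectors[outside, ] == 0))
  expect_error(solveDirichletEigen(gen, dom[1:3], 3), "more points")
})

test_that("free diffusion on (-1,1) reproduces the classical Dirichlet spectrum", {
  set.seed(42)
  X <- matrix(runif(4000, -1, 1), ncol = 1)
  gen <- buildGenerator(buildKernel(X, 0.001), alpha = 0.5)
  dom <- which(abs(X[, 1]) < 0.97)
  ds <- solveDirichletEigen(gen, dom, 3)
  ref <- -(pi * (1:3) / 2)^2
  expect_lt(max(abs(ds@eigenvalues / ref - 1)), 0.1)
})

test_that("the trapped-well spectrum sees the local (QSD-weighted) relaxation", {
  # samples conditioned to one well of the 1D double well approximate the
  # QSD-weighted generator; where v ~ 1 that operator coincides with the
  # full generator, so the conditioned cloud's first nonzero eigenvalue
  # must match the full-line intra-well relaxation mode (the eigenvalue
  # ABOVE the slow interwell one), not the interwell rate itself
  tr <- simulateOverdamped(doubleWell1D(), beta = 1, dt = 0.05,
                           nSteps = 6e4, x0 = 1, seed = 12, scheme = "lm")
  X <- coords(tr)
  Xw <- X[X[, 1] > 0, , drop = FALSE]      # condition on the right well
  idx <- round(seq(1, nrow(Xw), length.out = 1500))
  gen <- buildGenerator(buildKernel(Xw[idx, , drop = FALSE], 0.01),
                        alpha = 0.5)
  dec <- spectralDecompose(gen, 1)
  full <- chebyshevDirichlet(doubleWell1D(), 1, c(-3.5, 3.5), n = 384,
                             k = 3, checkConvergence = FALSE)
  intraWell <- full$values[3]              # 0, interwell, intra-well, ...
  expect_lt(abs(dec@values[2] - intraWell) / abs(intraWell), 0.2)
})
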