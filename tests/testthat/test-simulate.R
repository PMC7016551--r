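test_that("overdamped trajectories are seeded, sized and typed correctly", {
  tr0 <- simulateOverdamped(quadraticPotential(), 1, 0.01, 0, x0 = 2,
                            seed = 1)
  expect_equal(nPoints(tr0), 1L)
  expect_equal(coords(tr0)[1, ], 2)

  a <- simulateOverdamped(doubleWell1D(), 1, 0.05, 500, 1, seed = 42)
  b <- simulateOverdamped(doubleWell1D(), 1, 0.05, 500, 1, seed = 42)
  c <- simulateOverdamped(doubleWell1D(), 1, 0.05, 500, 1, seed = 43)
  expect_identical(coords(a), coords(b))
  expect_false(identical(coords(a), coords(c)))

  lm <- simulateOverdamped(doubleWell1D(), 1, 0.05, 500, 1, seed = 42,
                           scheme = "lm")
  expect_false(identical(coords(a), coords(lm)))
  expect_equal(lm@scheme, "lm")
})

test_that("zero noise reduces the integrator to gradient descent", {
  tr <- simulateOverdamped(quadraticPotential(), 1, 0.1, 200, 2, seed = 1,
                           noiseScale = 0)
  x <- coords(tr)[, 1]
  expect_true(all(diff(x) < 0))
  expect_lt(x[201], 1e-8)
})

test_that("the quadratic well equilibrates to the Boltzmann variance", {
  # stationary variance of V = x^2/2 at inverse temperature beta is
  # 1/beta; the Leimkuhler-Matthews step reproduces it exactly for this
  # potential, so the estimate is limited only by sampling
  tr <- simulateOverdamped(quadraticPotential(), beta = 1, dt = 0.05,
                           nSteps = 2e5, x0 = 0, seed = 7, scheme = "lm")
  x <- coords(tr)[, 1]
  second <- x[(length(x) %/% 2):length(x)]
  expect_gt(var(second), 0.9)
  expect_lt(var(second), 1.1)
})

test_that("long unbiased sampling matches the Boltzmann law (KS check)", {
  tr <- simulateOverdamped(quadraticPotential(), beta = 1, dt = 0.1,
                           nSteps = 1e6, x0 = 0, seed = 5, scheme = "lm")
  x <- coords(tr)[-(1:1000), 1]
  ks <- suppressWarnings(ks.test(x, pnorm, 0, 1))
  expect_lt(unname(ks$statistic), 0.01)
})

test_that("divergence is reported with its step index", {
  expect_error(
    simulateOverdamped(doubleWell1D(), 1, dt = 5, nSteps = 50, x0 = 2,
                       seed = 1, noiseScale = 0),
    "step")
})

test_that("Gaussian-hill bias evaluates to its closed form", {
  empty <- new("BiasState", centers = numeric(0), height = 1, width = 0.5,
               stride = 1L)
  expect_equal(evaluateBias(empty, 0.3), list(value = 0, derivative = 0))

  one <- new("BiasState", centers = 0, height = 1, width = 0.5, stride = 1L)
  expect_equal(evaluateBias(one, 0)$value, 1)
  expect_equal(evaluateBias(one, 0)$derivative, 0)
  expect_equal(evaluateBias(one, 0.5)$value, exp(-0.5))
  # exact derivative of the hill sum
  z <- 0.37
  expect_equal(evaluateBias(one, z)$derivative,
               -z / 0.25 * exp(-z^2 / 0.5))
})

test_that("metadynamics with zero hills is bit-identical to plain dynamics", {
  cvx <- list(value = function(p) p[1], grad = function(p) 1)
  res <- simulateMetadynamics(doubleWell1D(), cvx, 1, 0.05, 400,
                              hillHeight = 0, hillWidth = 0.3, stride = 50,
                              x0 = 1, seed = 9)
  ref <- simulateOverdamped(doubleWell1D(), 1, 0.05, 400, 1, seed = 9)
  expect_identical(coords(res$trajectory), coords(ref))
})

test_that("hills are deposited every stride steps", {
  cvx <- list(value = function(p) p[1], grad = function(p) 1)
  res <- simulateMetadynamics(doubleWell1D(), cvx, 1, 0.05, 1000,
                              hillHeight = 0.1, hillWidth = 0.3,
                              stride = 100, x0 = 1, seed = 9)
  expect_length(res$bias@centers, 10L)
  # accumulated bias carries across restarts
  res2 <- simulateMetadynamics(doubleWell1D(), cvx, 1, 0.05, 500,
                               hillHeight = 0.1, hillWidth = 0.3,
                               stride = 100, x0 = 1, seed = 10,
                               bias = res$bias)
  expect_length(res2$bias@centers, 15L)
})

test_that("metadynamics crosses the 2D barrier where plain dynamics stays trapped", {
  pot <- doubleWell2D(h = 2, w = 1)
  cvx <- list(value = function(p) p[1], grad = function(p) c(1, 0))
  budget <- 16000
  biased <- simulateMetadynamics(pot, cvx, beta = 10, dt = 0.02,
                                 nSteps = budget, hillHeight = 0.125,
                                 hillWidth = 0.25, stride = 250,
                                 x0 = c(1, 0), seed = 5, scheme = "lm")
  plain <- simulateOverdamped(pot, beta = 10, dt = 0.02, nSteps = budget,
                              x0 = c(1, 0), seed = 5, scheme = "lm")
  xb <- coords(biased$trajectory)[, 1]
  xp <- coords(plain)[, 1]
  expect_true(any(xb < -0.3))
  expect_false(any(xp < 0))
})
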