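test_that("free diffusion has the classical Dirichlet eigenvalues", {
  ed <- chebyshevDirichlet(flatPotential(1), 1, c(-1, 1), n = 128, k = 3)
  expect_true(ed$converged)
  expect_equal(ed$values, -(pi * (1:3) / 2)^2, tolerance = 1e-8)
  # general interval scaling
  ed2 <- chebyshevDirichlet(flatPotential(1), 1, c(-2.5, 2.5), n = 128,
                            k = 1)
  expect_equal(ed2$values[1], -(pi / 5)^2, tolerance = 1e-8)
})

test_that("doubling the grid leaves converged eigenvalues fixed", {
  a <- chebyshevDirichlet(quadraticPotential(), 1, c(-1, 1), n = 64, k = 1,
                          checkConvergence = FALSE)
  b <- chebyshevDirichlet(quadraticPotential(), 1, c(-1, 1), n = 128,
                          k = 1, checkConvergence = FALSE)
  expect_lt(abs(a$values[1] - b$values[1]), 1e-8)
})

test_that("the flat committor is the linear ramp", {
  cc <- chebyshevCommittor(flatPotential(1), 1, -1, 1, n = 64)
  expect_equal(cc$values, (cc$grid + 1) / 2, tolerance = 1e-8)
})

test_that("the 1D committor matches its quadrature closed form", {
  # q(x) = int_a^x e^{beta V} / int_a^b e^{beta V}
  co <- chebyshevCommittor(quadraticPotential(), 1, -1, 1, n = 256)
  Z <- integrate(function(s) exp(s^2 / 2), -1, 1)$value
  oracle <- vapply(co$grid, function(x)
    integrate(function(s) exp(s^2 / 2), -1, x)$value / Z, numeric(1))
  expect_lt(max(abs(co$values - oracle)), 1e-6)

  co2 <- chebyshevCommittor(doubleWell1D(), 2, -1.3, 1.3, n = 256)
  Z2 <- integrate(function(s) exp(2 * (s^2 - 1)^2), -1.3, 1.3)$value
  oracle2 <- vapply(co2$grid, function(x)
    integrate(function(s) exp(2 * (s^2 - 1)^2), -1.3, x)$value / Z2,
    numeric(1))
  expect_lt(max(abs(co2$values - oracle2)), 1e-6)
})

test_that("the QSD normalizes correctly and has the cosine ground state", {
  q <- chebyshevQSD(flatPotential(1), 1, L = 1, n = 128)
  expect_equal(sum(q@quadWeights * q@nu), 1, tolerance = 1e-8)
  expect_equal(chebInterp(q@grid, q@nu, 0), pi / 4, tolerance = 1e-8)
  expect_equal(q@lambda1, (pi / 2)^2, tolerance = 1e-8)
  # nu is proportional to cos(pi x / 2) for V = 0
  xs <- seq(-0.9, 0.9, by = 0.3)
  expect_equal(chebInterp(q@grid, q@nu, xs), pi / 4 * cos(pi * xs / 2),
               tolerance = 1e-8)
})

test_that("a constant eigenfunction gives the restricted Boltzmann density", {
  grid <- chebyshevDirichlet(quadraticPotential(), 1, c(-1, 1), n = 96,
                             k = 1)$grid
  q <- qsdDensity(rep(1, length(grid)), grid, quadraticPotential(), 1)
  Z <- integrate(function(s) exp(-s^2 / 2), -1, 1)$value
  xs <- seq(-0.8, 0.8, by = 0.4)
  expect_equal(chebInterp(q@grid, q@nu, xs), exp(-xs^2 / 2) / Z,
               tolerance = 1e-6)
  expect_error(qsdDensity(rep(-1, length(grid)), grid,
                          quadraticPotential(), 1), "positive")
})

test_that("the QSD eigenfunction approaches 1 at the well as the domain grows", {
  pot <- shiftedDoubleWell1D()
  devs <- vapply(c(2, 3, 5, 8), function(L) {
    q <- chebyshevQSD(pot, 1, L = L, n = 256)
    abs(qsdEigenfunctionAt(q, pot, 1, 1) - 1)
  }, numeric(1))
  # monotone decrease until the deviation reaches the spectral floor
  expect_true(all(diff(devs) < 0 | devs[-1] < 1e-8))
  expect_lt(devs[4], 0.05)
})
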