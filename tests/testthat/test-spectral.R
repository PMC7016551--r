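test_that("the trivial mode is constant and the spectrum is sorted", {
  dec <- spectralDecompose(ouGen2000(), 3)
  phi0 <- dec@vectors[, 1]
  expect_lt(sd(phi0) / abs(mean(phi0)), 1e-6)
  expect_true(all(diff(dec@values) <= 0))
  expect_true(all(dec@residuals < 1e-6))
})

test_that("eigenvector conventions: unit norm, positive largest entry", {
  dec <- spectralDecompose(ouGen2000(), 3)
  for (j in seq_len(ncol(dec@vectors))) {
    v <- dec@vectors[, j]
    expect_equal(sum(v^2), 1)
    expect_gt(v[which.max(abs(v))], 0)
  }
})

test_that("dense and ARPACK paths agree with a full dense-spectrum oracle", {
  # small random clouds: compare against eigen() of the full generator
  for (seed in 1:4) {
    set.seed(seed)
    m <- sample(4:6, 1)
    X <- matrix(rnorm(2 * m), ncol = 2)
    gen <- buildGenerator(buildKernel(X, 0.5), alpha = 0.5)
    dec <- spectralDecompose(gen, m - 1)
    oracle <- sort(Re(eigen(as.matrix(gen), only.values = TRUE)$values),
                   decreasing = TRUE)
    expect_equal(dec@values, oracle[seq_len(m)], tolerance = 1e-9)
  }
  # a larger cloud: ARPACK path vs dense path on the same generator
  set.seed(5)
  X <- matrix(rnorm(1600), ncol = 1)
  gen <- buildGenerator(buildKernel(X, 0.05), alpha = 0.5)
  arp <- spectralDecompose(gen, 3)          # m = 1600 takes the ARPACK path
  dense <- sort(Re(eigen(as.matrix(gen), only.values = TRUE)$values),
                decreasing = TRUE)[1:4]
  expect_equal(arp@values, dense, tolerance = 1e-8)
})

test_that("the Boltzmann-sampled quadratic well shows the OU spectrum ratio", {
  cl <- makeFixture("ou_1d", seed = 1, m = 4000)
  gen <- buildGenerator(buildKernel(cl, 0.05), alpha = 0.5)
  dec <- spectralDecompose(gen, 2)
  ratio <- dec@values[3] / dec@values[2]
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 2.2)
})

test_that("Nystrom extension is exact at training points", {
  cl <- makeFixture("ou_1d", seed = 2, m = 400)
  gen <- buildGenerator(buildKernel(cl, 0.05), alpha = 0.5)
  dec <- spectralDecompose(gen, 3)
  for (j in 1:2) {
    ext <- nystromExtend(dec, gen, cl, coords(cl), j = j)
    expect_lt(max(abs(ext - dec@vectors[, j + 1])) /
                max(abs(dec@vectors[, j + 1])), 1e-8)
  }
})

test_that("Nystrom extension of the constant mode is constant", {
  cl <- makeFixture("ou_1d", seed = 2, m = 400)
  gen <- buildGenerator(buildKernel(cl, 0.05), alpha = 0.5)
  dec <- spectralDecompose(gen, 2)
  new <- matrix(seq(-1, 1, length.out = 7), ncol = 1)
  e0 <- nystromExtend(dec, gen, cl, new, j = 0)
  expect_lt(sd(e0) / abs(mean(e0)), 1e-10)
})

test_that("antisymmetric eigenvectors extend to zero at the symmetry point", {
  X <- matrix(c(-1, 1), ncol = 1)
  gen <- buildGenerator(buildKernel(X, 0.5), alpha = 0.5)
  dec <- spectralDecompose(gen, 1)
  mid <- nystromExtend(dec, gen, X, matrix(0), j = 1)
  expect_lt(abs(mid), 1e-12)
})

test_that("a vanishing Markov eigenvalue blocks the extension", {
  X <- matrix(c(-1, 1), ncol = 1)
  gen <- buildGenerator(buildKernel(X, 0.5), alpha = 0.5)
  dec <- spectralDecompose(gen, 1)
  dec@values[2] <- -1 / gen@epsilon    # 1 + eps*lambda = 0 exactly
  expect_error(nystromExtend(dec, gen, X, matrix(0), j = 1), "vanishes")
})
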