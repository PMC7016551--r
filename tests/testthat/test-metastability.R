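test_that("threshold zero keeps only the two eigenvector extrema", {
  dec <- trappedDecomp()
  part <- identifyMetastableSets(dec, threshold = 0)
  phi1 <- dec@vectors[, 2]
  expect_identical(part@membersA, which.max(phi1))
  expect_identical(part@membersB, which.min(phi1))
})

test_that("the partition reproduces two well-separated blobs exactly", {
  tb <- makeFixture("two_blobs", seed = 3)
  gen <- buildGenerator(buildKernel(tb, 2), alpha = 0.5)
  dec <- spectralDecompose(gen, 2)
  phi1 <- dec@vectors[, 2]
  spread <- max(phi1) - min(phi1)
  part <- identifyMetastableSets(dec, threshold = spread / 2,
                                 embeddingDim = 1)
  labels <- rep(1:2, each = 500)
  expect_equal(sort(c(part@membersA, part@membersB)), 1:1000)
  expect_length(unique(labels[part@membersA]), 1L)
  expect_length(unique(labels[part@membersB]), 1L)
  expect_setequal(c(labels[part@membersA[1]], labels[part@membersB[1]]), 1:2)

  # sign structure: after centring, A and B lie on opposite signs of phi1
  centred <- phi1 - mean(phi1)
  expect_true(all(centred[part@membersA] > 0) ||
                all(centred[part@membersA] < 0))
  expect_true(all(sign(centred[part@membersA[1]]) !=
                    sign(centred[part@membersB])))
})

test_that("the partition is invariant under the eigenvector's global sign", {
  dec <- trappedDecomp()
  flipped <- dec
  flipped@vectors <- -dec@vectors
  phi1 <- dec@vectors[, 2]
  thr <- (max(phi1) - min(phi1)) / 3
  p1 <- identifyMetastableSets(dec, thr)
  p2 <- identifyMetastableSets(flipped, thr)
  # labels may swap; the unordered partition is identical
  expect_setequal(list(sort(p1@membersA), sort(p1@membersB)),
                  list(sort(p2@membersA), sort(p2@membersB)))
})

test_that("a constant first eigenvector is rejected with advice", {
  dec <- trappedDecomp()
  dec@vectors[, 2] <- 1 / sqrt(nrow(dec@vectors))
  expect_error(identifyMetastableSets(dec, 0.1), "constant")
})

test_that("trapped and global clouds correlate with the slow coordinate", {
  # inside one well of the 2D double well the first DC parametrizes y;
  # once both wells are covered it parametrizes x
  ccLocal <- localGlobalDCCorrelation(trappedDecomp(), coords(trappedCloud()))
  expect_gt(abs(ccLocal[2]), 0.9)
  expect_lt(abs(ccLocal[1]), 0.5)

  glob <- makeFixture("doublewell_2d_global", seed = 1, m = 2000)
  gen <- buildGenerator(buildKernel(glob, 0.1), alpha = 0.5)
  dec <- spectralDecompose(gen, 2)
  ccGlobal <- localGlobalDCCorrelation(dec, coords(glob))
  expect_gt(abs(ccGlobal[1]), 0.9)

  # zero-variance coordinate reports NA, not an error
  X <- cbind(coords(glob), 7)
  cc3 <- localGlobalDCCorrelation(dec, X)
  expect_true(is.na(cc3[3]))
})

test_that("identical windows give zero maxdiff and no exit flag", {
  ev <- matrix(rep(c(-1, -2, -3), each = 6), nrow = 6)
  s <- flagSpectrumExit(ev)
  expect_equal(s@means, rep(-2, 6))
  expect_equal(s@maxdiffs, rep(1, 6))
  expect_true(is.na(s@exitFlag))
})

test_that("a constructed change point is flagged at exactly its window", {
  # five windows near one spectrum with controlled jitter, then five near
  # a second spectrum shifted by 20 trailing deviations of the means
  s1 <- -c(1, 2, 3)
  jitter <- c(0, 0.01, -0.01, 0.005, -0.005)
  quiet <- t(vapply(jitter, function(j) s1 + j, numeric(3)))
  shift <- 20 * sd(rowMeans(quiet))
  moved <- t(vapply(jitter, function(j) s1 - shift + j, numeric(3)))
  windows <- rbind(quiet, moved)
  expect_gt(abs(mean(windows[6, ]) - mean(windows[5, ])) /
              sd(rowMeans(quiet)), 5)
  s <- flagSpectrumExit(windows, jumpFactor = 5)
  expect_identical(s@exitFlag, 6L)
})

test_that("the monitor recomputes window spectra along a trajectory", {
  tr <- simulateOverdamped(doubleWell2D(), beta = 10, dt = 0.1,
                           nSteps = 8000, x0 = c(1, 0), seed = 2,
                           scheme = "lm")
  mon <- spectrumMonitor(tr, windowSize = 250, subsample = 8, k = 3,
                         eps = 0.1)
  expect_equal(nrow(mon@eigenvalues), 4L)
  expect_true(all(mon@eigenvalues < 0))
  expect_equal(mon@means, rowMeans(mon@eigenvalues))
  expect_error(spectrumMonitor(tr, windowSize = 5000, subsample = 8,
                               k = 2, eps = 0.1), "exceeds")
})
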