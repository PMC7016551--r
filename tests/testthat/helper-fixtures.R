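# Shared lazily-built fixtures: heavy objects are constructed once per
# test run and reused across files.

.cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .cache)) assign(name, builder(), envir = .cache)
  get(name, envir = .cache)
}

ouCloud2000 <- function() cached("ou2000", function() {
  makeFixture("ou_1d", seed = 1, m = 2000)
})

ouGen2000 <- function() cached("ougen2000", function() {
  buildGenerator(buildKernel(ouCloud2000(), 0.05), alpha = 0.5)
})

trappedCloud <- function() cached("trapped", function() {
  makeFixture("doublewell_2d_trapped", seed = 1, m = 1200)
})

trappedDecomp <- function() cached("trappedDec", function() {
  gen <- buildGenerator(buildKernel(trappedCloud(), 0.1), alpha = 0.5)
  spectralDecompose(gen, 3)
})

# OU Dirichlet oracle on (-1, 1): the pseudo-spectral reference used by
# the point-cloud Dirichlet tests
ouOracle <- function() cached("ouOracle", function() {
  chebyshevDirichlet(quadraticPotential(), 1, c(-1, 1), n = 128, k = 4)
})

# full committor pipeline for the 2D double well at a temperature where
# both wells are visited; used by the acceptance committor criterion
committorStudy2D <- function(seed, m = 10000, eps = 0.1, beta = 2,
                             coreFraction = 0.25) {
  cloud <- makeFixture("doublewell_2d_global", seed = seed, m = m,
                       beta = beta)
  X <- coords(cloud)
  gen <- buildGenerator(buildKernel(cloud, eps), alpha = 0.5)
  dec <- spectralDecompose(gen, 2)
  phi1 <- dec@vectors[, 2L]
  spread <- max(phi1) - min(phi1)
  part <- identifyMetastableSets(dec, threshold = coreFraction * spread,
                                 embeddingDim = 1)
  com <- solveCommittor(gen, part@membersA, part@membersB)
  q <- committorValues(com)
  # orient: B is the x > 0 well so that q ~ P(reach right well first)
  if (mean(X[part@membersB, 1]) < 0) q <- 1 - q
  list(cloud = cloud, gen = gen, dec = dec, part = part, com = com,
       q = q, slab = which(abs(X[, 1]) < 0.1))
}
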