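Package: qsdmap
Title: Diffusion Maps, Quasi-Stationary Distributions and Committor
    Analysis for Stochastic Dynamics Point Clouds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Graph-Laplacian and target-measure diffusion-map
    approximations of the generator of overdamped Langevin dynamics on
    sampled point clouds, with point-cloud committor and Dirichlet
    eigenproblem solvers, a one-dimensional Chebyshev pseudo-spectral
    reference solver for quasi-stationary distributions, metastable-set
    identification from diffusion coordinates, spectrum-convergence exit
    detection, and an adaptive collective-variable learning loop coupling
    Fleming-Viot sampling, Pearson-correlation CV selection and
    metadynamics on built-in toy potentials.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
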