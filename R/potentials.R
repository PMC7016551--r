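#' Construct a potential
#'
#' Low-level constructor pairing an energy function with its exact
#' analytic gradient.  The built-in toy potentials below cover the
#' systems used throughout the package.
#'
#' @param name identifier.
#' @param dimension configuration-space dimension.
#' @param energy function: length-d numeric -> scalar energy.
#' @param gradient function: length-d numeric -> length-d gradient.
#' @param params named list of parameters (stored for provenance).
#' @return a \code{\linkS4class{Potential}}.
#' @export
makePotential <- function(name, dimension, energy, gradient,
                          params = list()) {
  new("Potential", name = name, params = params,
      dimension = as.integer(dimension), energy = energy,
      gradient = gradient)
}

#' Built-in toy potentials
#'
#' \describe{
#'   \item{\code{quadraticPotential()}}{\eqn{V(x) = x^2/2}: the
#'     Ornstein--Uhlenbeck well, whose time-rescaled generator
#'     \eqn{-\beta x \partial + \partial^2} has spectrum
#'     \eqn{0, -\beta, -2\beta, \ldots}.}
#'   \item{\code{doubleWell1D()}}{\eqn{V(x) = (x^2-1)^2}: symmetric 1D
#'     double well with minima at \eqn{\pm 1}.}
#'   \item{\code{shiftedDoubleWell1D()}}{\eqn{V(x) = ((x-1)^2-1)^2}:
#'     the same well shifted so one minimum sits at \eqn{x = 1} (used for
#'     the QSD domain-growth study).}
#'   \item{\code{doubleWell2D(h, w)}}{the two-dimensional double well
#'     \deqn{V(x,y) = \frac{1}{6}\big(4(-x^2-y^2+w)^2 + 2h(x^2-2)^2 +
#'       ((x+y)^2-w)^2 + ((x-y)^2-w)^2\big),}
#'     with two wells separated along \eqn{x} and a slow transverse
#'     \eqn{y} mode inside each well.  Defaults \code{h = 2},
#'     \code{w = 1}.}
#'   \item{\code{flatPotential(dimension)}}{\eqn{V = 0}: free Brownian
#'     motion, whose Dirichlet spectrum on an interval is classical.}
#' }
#'
#' @param h,w parameters of the 2D double well.
#' @param dimension dimension of the flat potential.
#' @return a \code{\linkS4class{Potential}}.
#' @export
quadraticPotential <- function() {
  makePotential("quadratic", 1L,
                energy = function(x) 0.5 * x[1]^2,
                gradient = function(x) x[1])
}

#' @rdname quadraticPotential
#' @export
doubleWell1D <- function() {
  makePotential("doublewell_1d", 1L,
                energy = function(x) (x[1]^2 - 1)^2,
                gradient = function(x) 4 * x[1] * (x[1]^2 - 1))
}

#' @rdname quadraticPotential
#' @export
shiftedDoubleWell1D <- function() {
  makePotential("doublewell_shifted_1d", 1L,
                energy = function(x) ((x[1] - 1)^2 - 1)^2,
                gradient = function(x) 4 * (x[1] - 1) * ((x[1] - 1)^2 - 1))
}

#' @rdname quadraticPotential
#' @export
doubleWell2D <- function(h = 2, w = 1) {
  energy <- function(x) {
    (4 * (-x[1]^2 - x[2]^2 + w)^2 + 2 * h * (x[1]^2 - 2)^2 +
       ((x[1] + x[2])^2 - w)^2 + ((x[1] - x[2])^2 - w)^2) / 6
  }
  gradient <- function(x) {
    u <- x[1]; v <- x[2]
    s <- u + v; d <- u - v
    gu <- (-16 * u * (w - u^2 - v^2) + 8 * h * u * (u^2 - 2) +
             4 * s * (s^2 - w) + 4 * d * (d^2 - w)) / 6
    gv <- (-16 * v * (w - u^2 - v^2) +
             4 * s * (s^2 - w) - 4 * d * (d^2 - w)) / 6
    c(gu, gv)
  }
  makePotential("doublewell_2d", 2L, energy, gradient,
                params = list(h = h, w = w))
}

#' @rdname quadraticPotential
#' @export
flatPotential <- function(dimension = 1L) {
  d <- as.integer(dimension)
  makePotential("flat", d,
                energy = function(x) 0,
                gradient = function(x) numeric(d))
}

#' Evaluate a potential and its gradient
#'
#' @param potential a \code{\linkS4class{Potential}}.
#' @param x numeric vector of the potential's dimension.
#' @return list with elements \code{energy} (scalar) and \code{gradient}
#'   (length-d vector), both finite.
#' @examples
#' evaluatePotential(doubleWell2D(h = 2, w = 1), c(0, 0))$energy  # 11/3
#' @export
evaluatePotential <- function(potential, x) {
  stopifnot(is(potential, "Potential"))
  x <- as.numeric(x)
  if (length(x) != potential@dimension)
    stop(sprintf("potential '%s' expects dimension %d, got %d",
                 potential@name, potential@dimension, length(x)))
  e <- potential@energy(x)
  g <- potential@gradient(x)
  if (!is.finite(e) || !all(is.finite(g)))
    stop("non-finite energy or gradient")
  list(energy = e, gradient = g)
}

## Gradient evaluated on a whole matrix of configurations (rows).
## Vectorized per-potential where it pays off; falls back to apply().
gradientAt <- function(potential, X) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  switch(potential@name,
    quadratic = X,
    flat = X * 0,
    doublewell_1d = 4 * X * (X^2 - 1),
    doublewell_shifted_1d = 4 * (X - 1) * ((X - 1)^2 - 1),
    doublewell_2d = {
      h <- potential@params$h; w <- potential@params$w
      u <- X[, 1L]; v <- X[, 2L]
      s <- u + v; d <- u - v
      cbind((-16 * u * (w - u^2 - v^2) + 8 * h * u * (u^2 - 2) +
               4 * s * (s^2 - w) + 4 * d * (d^2 - w)) / 6,
            (-16 * v * (w - u^2 - v^2) +
               4 * s * (s^2 - w) - 4 * d * (d^2 - w)) / 6)
    },
    {
      res <- apply(X, 1L, potential@gradient)
      if (is.matrix(res)) t(res) else matrix(res, ncol = 1L)
    })
}

## Energy on a matrix of configurations.
energyAt <- function(potential, X) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  switch(potential@name,
    quadratic = 0.5 * X[, 1L]^2,
    flat = numeric(nrow(X)),
    doublewell_1d = (X[, 1L]^2 - 1)^2,
    doublewell_shifted_1d = ((X[, 1L] - 1)^2 - 1)^2,
    doublewell_2d = {
      h <- potential@params$h; w <- potential@params$w
      u <- X[, 1L]; v <- X[, 2L]
      (4 * (-u^2 - v^2 + w)^2 + 2 * h * (u^2 - 2)^2 +
         ((u + v)^2 - w)^2 + ((u - v)^2 - w)^2) / 6
    },
    apply(X, 1L, potential@energy))
}
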