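#' Write a point cloud to disk
#'
#' Delimited text (one row per point, header naming the columns
#' \code{x1..xd} plus \code{weight} when weights are present, \code{#}
#' comment support) or a binary container (RDS).  Metadata is stored
#' alongside as a JSON document at \code{<path>.json}.
#'
#' @param cloud a \code{\linkS4class{PointCloud}}.
#' @param path output file path.
#' @param format \code{"delimited"} or \code{"container"}.
#' @return \code{path}, invisibly.
#' @export
writePointCloud <- function(cloud, path, format = c("delimited",
                                                    "container")) {
  format <- match.arg(format)
  stopifnot(is(cloud, "PointCloud"))
  if (format == "container") {
    saveRDS(cloud, path)
  } else {
    X <- cloud@points
    cols <- paste0("x", seq_len(ncol(X)))
    if (length(cloud@weights)) {
      X <- cbind(X, cloud@weights)
      cols <- c(cols, "weight")
    }
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(cols, collapse = " "), con)
    utils::write.table(format(X, digits = 17, trim = TRUE, scientific = TRUE),
                       con, quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  if (length(cloud@metadata))
    jsonlite::write_json(cloud@metadata, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a point cloud from disk
#'
#' Delimited dialect: whitespace- or comma-separated numeric rows,
#' \code{#} comment lines skipped anywhere, optional header row; a
#' trailing column named \code{weight} is honoured as per-point weights.
#' Ragged rows raise an error naming the offending line.  The container
#' format round-trips bit-exactly.
#'
#' @param path input file path.
#' @param format \code{"delimited"} or \code{"container"}.
#' @return a \code{\linkS4class{PointCloud}}.
#' @export
readPointCloud <- function(path, format = c("delimited", "container")) {
  format <- match.arg(format)
  if (format == "container") return(readRDS(path))
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineNo <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("empty point-cloud file: ", path)
  tokens <- strsplit(trimws(lines), "[,[:space:]]+")
  header <- character(0)
  if (any(is.na(suppressWarnings(as.numeric(tokens[[1L]]))))) {
    header <- tokens[[1L]]
    tokens <- tokens[-1L]
    lineNo <- lineNo[-1L]
    if (!length(tokens)) stop("point-cloud file has a header but no data")
  }
  ncols <- length(tokens[[1L]])
  bad <- which(lengths(tokens) != ncols)
  if (length(bad))
    stop(sprintf("ragged row at line %d: expected %d columns, found %d",
                 lineNo[bad[1L]], ncols, lengths(tokens)[bad[1L]]))
  vals <- suppressWarnings(as.numeric(unlist(tokens)))
  if (anyNA(vals)) {
    badTok <- which(is.na(as.numeric(unlist(tokens))))[1L]
    stop(sprintf("non-numeric value near line %d",
                 lineNo[ceiling(badTok / ncols)]))
  }
  X <- matrix(vals, ncol = ncols, byrow = TRUE)
  weights <- numeric(0)
  if (length(header) && tolower(header[length(header)]) == "weight") {
    weights <- X[, ncols]
    X <- X[, -ncols, drop = FALSE]
  }
  meta <- list()
  metaPath <- paste0(path, ".json")
  if (file.exists(metaPath))
    meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  new("PointCloud", points = X, weights = weights, metadata = meta)
}

#' Write a trajectory with its provenance
#'
#' Same dialects as \code{\link{writePointCloud}}; the JSON sidecar
#' records dt, beta, seed and scheme, so the trajectory can be
#' regenerated.
#'
#' @param trajectory a \code{\linkS4class{Trajectory}}.
#' @param path,format as in \code{\link{writePointCloud}}.
#' @return \code{path}, invisibly.
#' @export
writeTrajectory <- function(trajectory, path,
                            format = c("delimited", "container")) {
  cloud <- new("PointCloud", points = trajectory@points,
               weights = numeric(0),
               metadata = list(dt = trajectory@dt, beta = trajectory@beta,
                               seed = trajectory@seed,
                               scheme = trajectory@scheme))
  writePointCloud(cloud, path, format)
}

#' Export a generator matrix in coordinate text format
#'
#' Writes the nonzero entries as \code{row col value} triples (1-based,
#' full precision), preceded by a \code{#} header carrying the
#' construction parameters.
#'
#' @param generator a \code{\linkS4class{GeneratorMatrix}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
exportGenerator <- function(generator, path) {
  L <- generator@values
  if (is(L, "Matrix")) {
    T3 <- methods::as(methods::as(L, "generalMatrix"), "TsparseMatrix")
    df <- data.frame(row = T3@i + 1L, col = T3@j + 1L, value = T3@x)
  } else {
    nz <- which(L != 0, arr.ind = TRUE)
    df <- data.frame(row = nz[, 1L], col = nz[, 2L], value = L[nz])
  }
  df <- df[order(df$row, df$col), ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# generator kind=%s epsilon=%.17g alpha=%g m=%d",
                     generator@kind, generator@epsilon, generator@alpha,
                     nrow(L)), con)
  utils::write.table(format(df, digits = 17, trim = TRUE), con,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export a spectral decomposition as a two-block table
#'
#' First block: eigenvalues (one per line); second block: eigenvectors by
#' column.  Blocks are separated by \code{# eigenvectors}.
#'
#' @param decomposition a \code{\linkS4class{SpectralDecomposition}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
exportSpectrum <- function(decomposition, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# eigenvalues", con)
  writeLines(sprintf("%.17g", decomposition@values), con)
  writeLines("# eigenvectors", con)
  utils::write.table(format(decomposition@vectors, digits = 17,
                            trim = TRUE),
                     con, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Tabulate a metastable partition
#'
#' @param partition a \code{\linkS4class{MetastablePartition}}.
#' @param cloud the \code{\linkS4class{PointCloud}} (or matrix) it was
#'   computed on.
#' @param decomposition the matching
#'   \code{\linkS4class{SpectralDecomposition}}.
#' @return data.frame with the point index, coordinates, \eqn{\phi_1}
#'   and the set label (A, B or C).
#' @export
partitionTable <- function(partition, cloud, decomposition) {
  X <- asCoordMatrix(cloud)
  label <- rep("C", nrow(X))
  label[partition@membersA] <- "A"
  label[partition@membersB] <- "B"
  df <- data.frame(index = seq_len(nrow(X)), X,
                   phi1 = decomposition@vectors[, 2L], set = label)
  names(df)[2:(1 + ncol(X))] <- paste0("x", seq_len(ncol(X)))
  df
}

#' Tabulate a spectrum-monitor series
#'
#' @param series a \code{\linkS4class{SpectrumWindowSeries}}.
#' @return data.frame with window start step, eigenvalues, mean, maximal
#'   successive difference and the exit flag.
#' @export
monitorTable <- function(series) {
  E <- series@eigenvalues
  df <- data.frame(step = series@steps, E, mean = series@means,
                   maxdiff = series@maxdiffs,
                   exit = seq_len(nrow(E)) ==
                     ifelse(is.na(series@exitFlag), -1L, series@exitFlag))
  names(df)[2:(1 + ncol(E))] <- paste0("lambda", seq_len(ncol(E)))
  df
}

fixtureNames <- c("ou_1d", "doublewell_1d", "doublewell_shifted_1d",
                  "doublewell_2d_trapped", "doublewell_2d_global",
                  "two_blobs")

#' Deterministic study fixtures
#'
#' Named point clouds realizing the package's standard in-silico
#' experiments; deterministic from the seed.
#'
#' \describe{
#'   \item{ou_1d}{quadratic well \eqn{V = x^2/2}, \eqn{\beta = 1},
#'     Leimkuhler--Matthews trajectory at \eqn{\Delta t = 0.1},
#'     subsampled to m points (default 2000).}
#'   \item{doublewell_1d}{\eqn{V = (x^2-1)^2}, \eqn{\beta = 1},
#'     \eqn{\Delta t = 0.1}, \eqn{10^5} steps subsampled to m (default
#'     10^4).}
#'   \item{doublewell_shifted_1d}{\eqn{V = ((x-1)^2-1)^2}, otherwise as
#'     above.}
#'   \item{doublewell_2d_trapped}{2D double well (h = 2, w = 1) at
#'     \eqn{\beta = 10}, \eqn{\Delta t = 0.1}, started in the right well;
#'     the budget is far below the exit time at this temperature, so all
#'     points have x of one sign (default m = 1500).}
#'   \item{doublewell_2d_global}{same system, two equal-length
#'     trajectories started in the two wells and concatenated, so the
#'     cloud covers both wells (default m = 10^4).  The \code{beta}
#'     argument applies to this fixture only: the default \eqn{\beta =
#'     10} matches the local/global geometry study (where each walker
#'     stays in its well), while committor studies use a temperature at
#'     which the walkers actually cross (e.g. \eqn{\beta = 3}) so the
#'     transition region is populated.}
#'   \item{two_blobs}{500 + 500 Gaussian points (unit sigma) at centre
#'     separation 10 sigma; the unambiguous clustering fixture.}
#' }
#'
#' @param name one of the fixture names above.
#' @param seed integer seed.
#' @param m override the default number of points.
#' @param beta inverse temperature of the \code{doublewell_2d_global}
#'   fixture (ignored by the others).
#' @return a \code{\linkS4class{PointCloud}} with provenance metadata.
#' @export
makeFixture <- function(name, seed = 1L, m = NULL, beta = 10) {
  if (!name %in% fixtureNames)
    stop("unknown fixture '", name, "'; available: ",
         paste(fixtureNames, collapse = ", "))
  seed <- as.integer(seed)
  cloud <- switch(name,
    ou_1d = {
      if (is.null(m)) m <- 2000L
      tr <- simulateOverdamped(quadraticPotential(), beta = 1, dt = 0.1,
                               nSteps = max(20L * m, 20000L), x0 = 0,
                               seed = seed, scheme = "lm")
      subsampleCloud(tr, m, burnin = 100L)
    },
    doublewell_1d = {
      if (is.null(m)) m <- 10000L
      tr <- simulateOverdamped(doubleWell1D(), beta = 1, dt = 0.1,
                               nSteps = 100000L, x0 = 1, seed = seed,
                               scheme = "lm")
      subsampleCloud(tr, m, burnin = 100L)
    },
    doublewell_shifted_1d = {
      if (is.null(m)) m <- 10000L
      tr <- simulateOverdamped(shiftedDoubleWell1D(), beta = 1, dt = 0.1,
                               nSteps = 100000L, x0 = 1, seed = seed,
                               scheme = "lm")
      subsampleCloud(tr, m, burnin = 100L)
    },
    doublewell_2d_trapped = {
      if (is.null(m)) m <- 1500L
      tr <- simulateOverdamped(doubleWell2D(h = 2, w = 1), beta = 10,
                               dt = 0.1, nSteps = 30000L, x0 = c(1, 0),
                               seed = seed, scheme = "lm")
      subsampleCloud(tr, m, burnin = 200L)
    },
    doublewell_2d_global = {
      if (is.null(m)) m <- 10000L
      pot <- doubleWell2D(h = 2, w = 1)
      half <- ceiling(m / 2)
      trR <- simulateOverdamped(pot, beta = beta, dt = 0.1,
                                nSteps = 50000L, x0 = c(1, 0),
                                seed = deriveSeed(seed, 1L), scheme = "lm")
      trL <- simulateOverdamped(pot, beta = beta, dt = 0.1,
                                nSteps = 50000L, x0 = c(-1, 0),
                                seed = deriveSeed(seed, 2L), scheme = "lm")
      X <- rbind(coords(subsampleCloud(trR, half, burnin = 200L)),
                 coords(subsampleCloud(trL, m - half, burnin = 200L)))
      new("PointCloud", points = X, weights = numeric(0), metadata = list())
    },
    two_blobs = {
      set.seed(seed)
      X <- rbind(matrix(rnorm(1000L), 500L, 2L),
                 matrix(rnorm(1000L), 500L, 2L) +
                   rep(c(10, 0), each = 500L))
      new("PointCloud", points = X, weights = numeric(0), metadata = list())
    })
  cloud@metadata <- c(cloud@metadata,
                      list(fixture = name, seed = seed, m = nrow(cloud@points)))
  cloud
}

#' Checksum of a point cloud
#'
#' Order-sensitive numeric signature used by the fixture tests to assert
#' bit-reproducibility.
#'
#' @param cloud a \code{\linkS4class{PointCloud}} (or matrix).
#' @return character checksum.
#' @export
cloudChecksum <- function(cloud) {
  X <- asCoordMatrix(cloud)
  s <- c(dim(X), sum(X * seq_along(X)), sum(X), sum(X^2))
  paste(sprintf("%.15g", s), collapse = "|")
}

#' Read a run configuration
#'
#' JSON document of parameters and seeds; unknown keys are rejected so a
#' typo cannot silently fall back to a default.
#'
#' @param path JSON file path.
#' @param allowed character vector of permitted keys (NULL accepts all).
#' @return named list.
#' @export
readRunConfig <- function(path, allowed = NULL) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(allowed)) {
    unknown <- setdiff(names(cfg), allowed)
    if (length(unknown))
      stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  cfg
}
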