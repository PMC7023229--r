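# Kohonen self-organizing map engine: normalization, winner search,
# neighborhood, training schedules, mapping and quantization error.

#' Min-max normalize the columns of a matrix
#'
#' Maps every non-constant column onto `[0, 1]` via
#' `x' = (x - min) / (max - min)` and returns a scale record that allows the
#' exact inverse transform. Constant columns carry no information for
#' distance-based learning; they are mapped to 0.5 everywhere and flagged as
#' degenerate in the scale record rather than aborting the run.
#'
#' @param x numeric matrix or data.frame (objects x features), no missing
#'   values.
#' @return A list with elements `data` (normalized numeric matrix) and
#'   `scale` (data.frame with columns `feature`, `min`, `max`, `constant`).
#' @seealso [denormalizeColumns()] for the inverse transform.
#' @examples
#' nm <- normalizeColumns(cbind(a = c(0, 5, 10), b = c(7, 7, 7)))
#' nm$data
#' nm$scale
#' @export
normalizeColumns <- function(x) {
  x <- .asNumericMatrix(x)
  if (nrow(x) < 1L || ncol(x) < 1L)
    stop("matrix must have at least one row and one column")
  mins <- apply(x, 2L, min)
  maxs <- apply(x, 2L, max)
  constant <- maxs == mins
  out <- x
  for (j in seq_len(ncol(x))) {
    if (constant[j]) {
      out[, j] <- 0.5
    } else {
      out[, j] <- (x[, j] - mins[j]) / (maxs[j] - mins[j])
    }
  }
  scale <- data.frame(
    feature = colnames(x) %||% paste0("v", seq_len(ncol(x))), min = unname(mins), max = unname(maxs),
    constant = unname(constant), stringsAsFactors = FALSE)
  list(data = out, scale = scale)
}

#' Invert a min-max normalization
#'
#' @param x normalized numeric matrix (columns matching the scale record).
#' @param scale scale record from [normalizeColumns()].
#' @return Matrix on the original scale. Constant columns are restored to
#'   their recorded constant value.
#' @export
denormalizeColumns <- function(x, scale) {
  x <- .asNumericMatrix(x)
  if (ncol(x) != nrow(scale))
    stop("column count does not match the scale record")
  out <- x
  for (j in seq_len(ncol(x))) {
    if (scale$constant[j]) {
      out[, j] <- scale$min[j]
    } else {
      out[, j] <- x[, j] * (scale$max[j] - scale$min[j]) + scale$min[j]
    }
  }
  out
}

#' Chebyshev distance between two neurons on the grid
#'
#' The grid metric used by the neighborhood function: square rings around the
#' winner, planar (non-toroidal) boundaries.
#'
#' @param grid a [GridSpec-class].
#' @param a,b neuron coordinates, integer vectors `c(i, j)` (1-based).
#' @return Non-negative integer `max(|ai - bi|, |aj - bj|)`.
#' @examples
#' topoDistance(gridSpec(5, 5), c(1, 1), c(3, 4))
#' @export
topoDistance <- function(grid, a, b) {
  stopifnot(is(grid, "GridSpec"))
  .checkNeuron(grid, a)
  .checkNeuron(grid, b)
  max(abs(a[1L] - b[1L]), abs(a[2L] - b[2L]))
}

#' Triangular neighborhood weight
#'
#' `a = max(0, 1 - d / (r + 1))`: equal to 1 at the winner, decays linearly
#' with topological distance, and reaches 0 at `d >= r + 1`. Vectorized over
#' `d`.
#'
#' @param d topological distance(s), >= 0.
#' @param radius neighborhood radius, >= 0.
#' @return Weight(s) in `[0, 1]`, non-increasing in `d`.
#' @examples
#' neighborhoodWeight(0:3, radius = 2)
#' @export
neighborhoodWeight <- function(d, radius) {
  if (any(!is.finite(d)) || any(d < 0)) stop("'d' must be non-negative")
  if (length(radius) != 1L || !is.finite(radius) || radius < 0)
    stop("'radius' must be a single non-negative number")
  pmax(0, 1 - d / (radius + 1))
}

#' Find the winning neuron for one input vector
#'
#' Returns the neuron whose weight vector minimizes the Euclidean distance to
#' `x`; exact ties are broken deterministically by the smallest row-major
#' index `(i - 1) * ny + j`.
#'
#' @param model a [SOMModel-class] (trained or initialized).
#' @param x numeric feature vector of length `ncol(somWeights(model))`.
#' @return A list with elements `row`, `col`, `index` (row-major, 1-based)
#'   and `distance`.
#' @export
winnerNeuron <- function(model, x) {
  stopifnot(is(model, "SOMModel"))
  x <- as.numeric(x)
  if (length(x) != ncol(model@weights))
    stop(sprintf("input vector has length %d but the model expects %d features",
                 length(x), ncol(model@weights)))
  res <- cpp_map_objects(model@weights, matrix(x, nrow = 1L))
  idx <- res$winner[1L]
  ny <- model@grid@ny
  list(row = (idx - 1L) %/% ny + 1L, col = (idx - 1L) %% ny + 1L,
       index = idx, distance = res$distance[1L])
}

# epoch schedules: linear interpolation start -> end
.schedule <- function(start, end, epochs) {
  if (epochs == 1L) return(start)
  seq(start, end, length.out = epochs)
}

# run code under a temporary RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# deterministic derived seed (kept below 2^31 - 1); exact in double arithmetic
.deriveSeed <- function(seed, k) {
  as.integer(((as.numeric(seed) %% 1000003) * 2039 + as.numeric(k) * 7919 + 1) %%
               2147483647)
}

# initial weights and per-epoch presentation orders, drawn from the run seed
.somInit <- function(nNeurons, nFeatures, nTargets, nObj, epochs, seed) {
  .withSeed(seed, {
    W0x <- matrix(stats::runif(nNeurons * nFeatures), nNeurons, nFeatures)
    W0y <- if (nTargets > 0L)
      matrix(stats::runif(nNeurons * nTargets), nNeurons, nTargets)
    else matrix(numeric(0), nNeurons, 0L)
    orders <- matrix(0L, epochs, nObj)
    for (e in seq_len(epochs)) orders[e, ] <- sample.int(nObj)
    list(W0x = W0x, W0y = W0y, orders = orders)
  })
}

.checkNormalized <- function(x, what) {
  if (anyNA(x)) stop(sprintf("'%s' must not contain missing values", what))
  if (any(x < -0.001 | x > 1.001))
    stop(sprintf(
      "'%s' contains values outside [0, 1]; normalize first (see normalizeColumns())",
      what))
}

.checkNeuron <- function(grid, a) {
  if (length(a) != 2L || anyNA(a) || a[1L] < 1L || a[1L] > grid@nx ||
      a[2L] < 1L || a[2L] > grid@ny || any(a != floor(a)))
    stop("neuron coordinates out of grid")
}

.resolveConfig <- function(config, grid) {
  if (is.na(config@radiusStart))
    config@radiusStart <- max(grid@nx, grid@ny) - 1
  if (config@radiusStart < config@radiusEnd)
    stop("resolved radiusStart is smaller than radiusEnd")
  config
}

#' Train a self-organizing Kohonen map
#'
#' Sequential competitive learning: each epoch presents every object once in
#' a seed-determined, reshuffled order; for each presentation the Euclidean
#' winner is found and every neuron within the current neighborhood radius is
#' moved toward the object by `eta(t) * a(dTopo, r(t)) * (x - w)`, with the
#' triangular neighborhood of [neighborhoodWeight()] on the Chebyshev grid
#' metric. Learning rate and radius interpolate linearly across epochs.
#' Training is fully deterministic under the configuration seed: identical
#' seed and inputs give bit-identical weights.
#'
#' @param data numeric matrix (objects x features) normalized to `[0, 1]`
#'   (see [normalizeColumns()]).
#' @param grid a [GridSpec-class].
#' @param config a [TrainConfig-class]; `radiusStart = NA` resolves to
#'   `max(nx, ny) - 1`.
#' @return A trained [SOMModel-class].
#' @examples
#' X <- normalizeColumns(matrix(rnorm(60), 20, 3))$data
#' m <- trainSOM(X, gridSpec(3, 3), trainConfig(epochs = 20, seed = 1))
#' quantizationError(m, X)
#' @export
trainSOM <- function(data, grid, config = trainConfig()) {
  stopifnot(is(grid, "GridSpec"), is(config, "TrainConfig"))
  data <- .asNumericMatrix(data)
  if (nrow(data) < 1L) stop("'data' must contain at least one object")
  .checkNormalized(data, "data")
  config <- .resolveConfig(config, grid)
  nNeurons <- grid@nx * grid@ny
  init <- .somInit(nNeurons, ncol(data), 0L, nrow(data), config@epochs,
                   config@seed)
  fit <- cpp_train_cpann(data, init$W0y, init$W0x, init$W0y, init$orders,
                         .schedule(config@etaStart, config@etaEnd, config@epochs),
                         .schedule(config@radiusStart, config@radiusEnd,
                                   config@epochs),
                         grid@nx, grid@ny)
  new("SOMModel", grid = grid, weights = fit$Wx,
      featureNames = colnames(data) %||% paste0("f", seq_len(ncol(data))),
      config = config, trained = TRUE)
}

#' Map objects onto a trained SOM
#'
#' Applies [winnerNeuron()] independently to each row of `data`; the result
#' is therefore invariant to object order.
#'
#' @param model a trained [SOMModel-class].
#' @param data numeric matrix (objects x features), feature count matching
#'   the model.
#' @return data.frame with columns `id`, `row`, `col`, `index`, `distance`
#'   (Euclidean, normalized-feature units).
#' @export
mapObjects <- function(model, data) {
  stopifnot(is(model, "SOMModel"))
  data <- .asNumericMatrix(data)
  if (ncol(data) != ncol(model@weights))
    stop(sprintf("data has %d features but the model expects %d",
                 ncol(data), ncol(model@weights)))
  res <- cpp_map_objects(model@weights, data)
  ny <- model@grid@ny
  data.frame(
    id = rownames(data) %||% paste0("obj", seq_len(nrow(data))),
    row = (res$winner - 1L) %/% ny + 1L,
    col = (res$winner - 1L) %% ny + 1L,
    index = res$winner,
    distance = res$distance,
    stringsAsFactors = FALSE)
}

#' Quantization error of a SOM on a dataset
#'
#' Mean Euclidean distance from each object to its winning neuron's weight
#' vector; the standard training-quality diagnostic for Kohonen maps.
#'
#' @inheritParams mapObjects
#' @return Single non-negative number.
#' @export
quantizationError <- function(model, data) {
  data <- .asNumericMatrix(data)
  if (nrow(data) < 1L) stop("'data' must contain at least one object")
  mean(mapObjects(model, data)$distance)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# coerce to a checked numeric matrix, naming the first offending cell
.asNumericMatrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(as.numeric(x), nrow = NROW(x))
  if (!is.numeric(x)) stop("matrix must be numeric")
  if (anyNA(x) || any(!is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    rn <- rownames(x)[bad[1L]] %||% bad[1L]
    cn <- colnames(x)[bad[2L]] %||% bad[2L]
    stop(sprintf("missing or non-finite value at row '%s', column '%s'", rn, cn))
  }
  x
}
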