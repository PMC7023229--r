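# Counter-propagation ANN: Kohonen input layer + one-to-one output layer,
# prediction as table lookup, fit metrics, leave-one-out cross-validation.

#' Train a counter-propagation neural network
#'
#' A CPANN has a Kohonen input layer trained on the descriptors and an output
#' layer of identical geometry trained toward the targets. For every
#' presentation the winner is chosen from the input layer only; the input
#' weights move toward `x` and the output weights toward `y` with the same
#' `eta(t) * a(dTopo, r(t))` factor, so the two layers stay in one-to-one
#' neuron correspondence and the trained network acts as a topology-smoothed
#' lookup table.
#'
#' @param X numeric matrix (objects x features) normalized to `[0, 1]`.
#' @param y numeric vector or matrix (objects x targets) normalized to
#'   `[0, 1]`, row-aligned with `X`.
#' @param grid a [GridSpec-class].
#' @param config a [TrainConfig-class].
#' @param targetScale optional scale record from [normalizeColumns()] for the
#'   targets, stored for de-normalized prediction.
#' @return A [CPANNModel-class].
#' @examples
#' X <- normalizeColumns(matrix(runif(100), 50, 2))$data
#' y <- (X[, 1] + X[, 2]) / 2
#' m <- trainCPANN(X, y, gridSpec(6, 6), trainConfig(epochs = 30, seed = 1))
#' fitMetrics(y, predict(m, X))$r2
#' @export
trainCPANN <- function(X, y, grid, config = trainConfig(),
                       targetScale = NULL) {
  stopifnot(is(grid, "GridSpec"), is(config, "TrainConfig"))
  X <- .asNumericMatrix(X)
  yIsVector <- is.null(dim(y))
  Y <- .asNumericMatrix(if (yIsVector) matrix(y, ncol = 1L,
                                              dimnames = list(names(y), "y"))
                        else y)
  if (nrow(X) != nrow(Y))
    stop(sprintf("X has %d rows but y has %d; they must be row-aligned",
                 nrow(X), nrow(Y)))
  .checkNormalized(X, "X")
  if (any(Y < -0.001 | Y > 1.001))
    stop("targets lie outside [0, 1]; normalize first (see normalizeColumns())")
  config <- .resolveConfig(config, grid)
  nNeurons <- grid@nx * grid@ny
  init <- .somInit(nNeurons, ncol(X), ncol(Y), nrow(X), config@epochs,
                   config@seed)
  fit <- cpp_train_cpann(X, Y, init$W0x, init$W0y, init$orders,
                         .schedule(config@etaStart, config@etaEnd, config@epochs),
                         .schedule(config@radiusStart, config@radiusEnd,
                                   config@epochs),
                         grid@nx, grid@ny)
  som <- new("SOMModel", grid = grid, weights = fit$Wx,
             featureNames = colnames(X) %||% paste0("f", seq_len(ncol(X))),
             config = config, trained = TRUE)
  new("CPANNModel", som = som, outputWeights = fit$Wy,
      targetNames = colnames(Y) %||% paste0("t", seq_len(ncol(Y))),
      targetScale = if (is.null(targetScale)) list() else
        list(scale = targetScale))
}

#' Predict from a trained CPANN
#'
#' Looks up the output-layer weight vector of the input-layer winner for each
#' query. Predictions are pure lookups: repeated calls with identical inputs
#' return identical outputs, and at most `nx * ny` distinct values occur over
#' any query set.
#'
#' @param object a [CPANNModel-class].
#' @param newdata numeric vector (one query) or matrix (queries x features).
#' @param denormalize if `TRUE`, map predictions back to original target
#'   units using the scale record stored at training time.
#' @param ... ignored.
#' @return For a vector query, a named numeric vector of targets; for a
#'   matrix, a queries x targets matrix.
#' @export
setMethod("predict", "CPANNModel",
          function(object, newdata, denormalize = FALSE, ...) {
  single <- is.null(dim(newdata))
  Xq <- if (single) matrix(as.numeric(newdata), nrow = 1L) else
    .asNumericMatrix(newdata)
  if (ncol(Xq) != ncol(object@som@weights))
    stop(sprintf("query has %d features but the model expects %d",
                 ncol(Xq), ncol(object@som@weights)))
  res <- cpp_map_objects(object@som@weights, Xq)
  pred <- object@outputWeights[res$winner, , drop = FALSE]
  colnames(pred) <- object@targetNames
  rownames(pred) <- rownames(Xq)
  if (denormalize) {
    if (is.null(object@targetScale$scale))
      stop("no target scale record stored; train with targetScale= to denormalize")
    pred <- denormalizeColumns(pred, object@targetScale$scale)
  }
  if (single) pred[1L, ] else pred
})

#' Goodness-of-fit metrics for observed vs. predicted values
#'
#' `r2` is the squared Pearson correlation between observed and predicted
#' (the QSAR convention for both training R-squared and cross-validated
#' Q-squared); `rmse` is the root-mean-square error on the scale of the
#' inputs. The regression-style `1 - SSres / SStot` variant is also returned
#' as `r2ss` for transparency (it can be negative for poor models).
#'
#' @param observed,predicted numeric vectors of equal length >= 3; `observed`
#'   must not be constant.
#' @return List with elements `r2`, `rmse`, `n`, `r2ss`.
#' @examples
#' fitMetrics(c(0, 1, 2), c(0, 1, 5))
#' @export
fitMetrics <- function(observed, predicted) {
  observed <- as.numeric(observed)
  predicted <- as.numeric(predicted)
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length")
  if (length(observed) < 3L) stop("need at least 3 observations")
  if (anyNA(observed) || anyNA(predicted)) stop("missing values not allowed")
  if (stats::sd(observed) == 0)
    stop("observed values are constant; correlation is undefined")
  r <- suppressWarnings(stats::cor(observed, predicted))
  if (is.na(r)) r <- 0  # constant predictions carry no correlation signal
  list(r2 = r^2,
       rmse = sqrt(mean((observed - predicted)^2)),
       n = length(observed),
       r2ss = 1 - sum((observed - predicted)^2) /
         sum((observed - mean(observed))^2))
}

#' Leave-one-out cross-validation of a CPANN
#'
#' For each object `k` a fresh CPANN is trained on all other objects, with a
#' per-fold seed derived deterministically from `config@seed` and `k`, and
#' object `k` is predicted by the held-out model. `q2cv` and `rmsecv` are
#' computed only from the held-out predictions.
#'
#' @param X numeric matrix (objects x features) in `[0, 1]`.
#' @param y numeric vector of normalized targets (length `nrow(X)`, >= 3).
#' @param grid a [GridSpec-class].
#' @param config a [TrainConfig-class]; `config@seed` is the master seed.
#' @return List of class `fdCVResult`: `predictions` (data.frame `id`,
#'   `observed`, `predicted`), `q2cv` (squared Pearson of observed vs.
#'   held-out predictions), `rmsecv`, `q2ss` (the `1 - PRESS/SS` variant),
#'   `n`.
#' @export
looCV <- function(X, y, grid, config = trainConfig()) {
  X <- .asNumericMatrix(X)
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  n <- nrow(X)
  if (n < 3L) stop("leave-one-out requires at least 3 objects")
  pred <- numeric(n)
  for (k in seq_len(n)) {
    cfgK <- config
    cfgK@seed <- .deriveSeed(config@seed, k)
    mK <- trainCPANN(X[-k, , drop = FALSE], y[-k], grid, cfgK)
    pred[k] <- unname(predict(mK, X[k, ]))
  }
  fm <- fitMetrics(y, pred)
  structure(list(
    predictions = data.frame(
      id = rownames(X) %||% paste0("obj", seq_len(n)),
      observed = y, predicted = pred, stringsAsFactors = FALSE),
    q2cv = fm$r2, rmsecv = fm$rmse, q2ss = fm$r2ss, n = n),
    class = "fdCVResult")
}

#' @export
print.fdCVResult <- function(x, ...) {
  cat(sprintf("Leave-one-out CV, n = %d: Q2 = %.4f (RMSE = %.4f, 1-PRESS/SS = %.4f)\n",
              x$n, x$q2cv, x$rmsecv, x$q2ss))
  invisible(x)
}
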