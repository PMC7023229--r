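#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib fdQSAR, .registration = TRUE
NULL

#' Rectangular planar SOM grid
#'
#' A `GridSpec` describes the neuron lattice of a Kohonen map: `nx` rows by
#' `ny` columns, planar (non-toroidal) topology. Neurons are addressed by
#' 1-based coordinates `(i, j)` with `1 <= i <= nx`, `1 <= j <= ny`; the
#' row-major linear index is `(i - 1) * ny + j`, which is also the
#' deterministic tie-break order used throughout the package.
#'
#' @slot nx integer, number of rows (>= 1).
#' @slot ny integer, number of columns (>= 1).
#' @export
setClass("GridSpec", representation(nx = "integer", ny = "integer"))

setValidity("GridSpec", function(object) {
  if (length(object@nx) != 1L || length(object@ny) != 1L)
    return("nx and ny must be single integers")
  if (is.na(object@nx) || is.na(object@ny))
    return("nx and ny must not be NA")
  if (object@nx < 1L || object@ny < 1L)
    return("grid dimensions must be >= 1")
  TRUE
})

#' Construct a SOM grid specification
#'
#' @param nx number of rows (positive integer).
#' @param ny number of columns (positive integer).
#' @return A [GridSpec-class] object.
#' @examples
#' gridSpec(5, 5)
#' @export
gridSpec <- function(nx, ny) {
  nx <- .asCount(nx, "nx")
  ny <- .asCount(ny, "ny")
  new("GridSpec", nx = nx, ny = ny)
}

#' SOM / CPANN training configuration
#'
#' Training schedules: across `epochs` epochs the learning rate interpolates
#' linearly from `etaStart` down to `etaEnd` and the neighborhood radius from
#' `radiusStart` down to `radiusEnd`. Each object is presented once per epoch
#' in a seed-determined, per-epoch reshuffled order. `radiusStart = NA` means
#' "resolve to `max(nx, ny) - 1` at training time".
#'
#' @slot epochs integer, number of learning epochs.
#' @slot etaStart,etaEnd learning-rate bounds in (0, 1], `etaStart >= etaEnd`.
#' @slot radiusStart,radiusEnd neighborhood radius bounds (grid units),
#'   `radiusStart >= radiusEnd >= 0`; `radiusStart` may be `NA` (auto).
#' @slot seed integer seed controlling weight initialization and presentation
#'   order; identical seed and inputs give bit-identical trained weights.
#' @export
setClass("TrainConfig", representation(
  epochs = "integer", etaStart = "numeric", etaEnd = "numeric",
  radiusStart = "numeric", radiusEnd = "numeric", seed = "integer"
))

setValidity("TrainConfig", function(object) {
  if (object@epochs < 1L) return("epochs must be >= 1")
  if (!(object@etaStart > 0 && object@etaStart <= 1))
    return("etaStart must lie in (0, 1]")
  if (!(object@etaEnd > 0 && object@etaEnd <= 1))
    return("etaEnd must lie in (0, 1]")
  if (object@etaStart < object@etaEnd)
    return("etaStart must be >= etaEnd")
  if (!is.na(object@radiusStart)) {
    if (object@radiusStart < 0) return("radiusStart must be >= 0")
    if (object@radiusStart < object@radiusEnd)
      return("radiusStart must be >= radiusEnd")
  }
  if (object@radiusEnd < 0) return("radiusEnd must be >= 0")
  if (is.na(object@seed)) return("seed must not be NA")
  TRUE
})

#' Construct a training configuration
#'
#' Defaults follow the study settings (100 learning epochs) with conventional
#' schedules: learning rate 0.5 -> 0.01 and radius `max(nx, ny) - 1` -> 0,
#' both linearly interpolated across epochs.
#'
#' @param epochs number of learning epochs (default 100).
#' @param etaStart,etaEnd learning-rate schedule endpoints.
#' @param radiusStart neighborhood radius at epoch 1; `NA` (default) resolves
#'   to `max(nx, ny) - 1` for the grid being trained.
#' @param radiusEnd neighborhood radius at the final epoch.
#' @param seed integer seed for initialization and presentation order.
#' @return A [TrainConfig-class] object.
#' @examples
#' trainConfig(epochs = 100, seed = 42)
#' @export
trainConfig <- function(epochs = 100L, etaStart = 0.5, etaEnd = 0.01,
                        radiusStart = NA_real_, radiusEnd = 0, seed = 1L) {
  new("TrainConfig",
      epochs = .asCount(epochs, "epochs"),
      etaStart = as.numeric(etaStart), etaEnd = as.numeric(etaEnd),
      radiusStart = as.numeric(radiusStart), radiusEnd = as.numeric(radiusEnd),
      seed = as.integer(seed))
}

#' Trained self-organizing map
#'
#' Weight vectors live in the normalized descriptor space: inputs are expected
#' in `[0, 1]` (see [normalizeColumns()]) and, because every update moves a
#' weight toward a data point, trained weights stay within `[-0.1, 1.1]`.
#'
#' @slot grid a [GridSpec-class].
#' @slot weights numeric matrix, one row per neuron in row-major neuron order,
#'   one column per feature.
#' @slot featureNames character vector naming the feature space.
#' @slot config the [TrainConfig-class] used for training.
#' @slot trained logical flag.
#' @export
setClass("SOMModel", representation(
  grid = "GridSpec", weights = "matrix", featureNames = "character",
  config = "TrainConfig", trained = "logical"
))

setValidity("SOMModel", function(object) {
  nNeurons <- object@grid@nx * object@grid@ny
  if (nrow(object@weights) != nNeurons)
    return(sprintf("weights must have %d rows (one per neuron)", nNeurons))
  if (ncol(object@weights) != length(object@featureNames))
    return("weights column count must equal length(featureNames)")
  if (anyNA(object@weights)) return("weights must not contain NA")
  TRUE
})

#' Counter-propagation network model
#'
#' A CPANN couples a Kohonen input layer (trained on descriptors) to an output
#' layer of identical geometry holding one target vector per neuron. The
#' winner is always chosen from the input layer; prediction returns the output
#' weights of the winning neuron, so the model behaves as a smooth lookup
#' table with at most `nx * ny` distinct predictions.
#'
#' @slot som the input-layer [SOMModel-class].
#' @slot outputWeights numeric matrix, neurons x targets, in normalized target
#'   units.
#' @slot targetNames character vector of target names.
#' @slot targetScale list with the min/max scale record of the targets (as
#'   returned by [normalizeColumns()]), or an empty list if targets were
#'   supplied pre-normalized without a record.
#' @export
setClass("CPANNModel", representation(
  som = "SOMModel", outputWeights = "matrix", targetNames = "character",
  targetScale = "list"
))

setValidity("CPANNModel", function(object) {
  if (nrow(object@outputWeights) != nrow(object@som@weights))
    return("outputWeights must have one row per neuron")
  if (ncol(object@outputWeights) != length(object@targetNames))
    return("outputWeights column count must equal length(targetNames)")
  if (ncol(object@outputWeights) < 1L) return("at least one target required")
  TRUE
})

#' Min/max-distance selection from a trained SOM
#'
#' Result of [reduceBySOM()]: per occupied neuron, the member object with the
#' smallest and the member with the largest Euclidean distance to the neuron
#' weight vector; the deduplicated union forms the selected set, so
#' `length(selectedIds(x)) <= 2 * number of occupied neurons`.
#'
#' @slot mapping data.frame with columns `id`, `row`, `col`, `distance` (one
#'   row per mapped object).
#' @slot perNeuron data.frame with columns `row`, `col`, `n`, `minId`,
#'   `minDistance`, `maxId`, `maxDistance` (one row per occupied neuron).
#' @slot selected character vector of selected object IDs (deduplicated, in
#'   neuron row-major order, min before max).
#' @slot model the trained [SOMModel-class].
#' @export
setClass("SOMSelection", representation(
  mapping = "data.frame", perNeuron = "data.frame", selected = "character",
  model = "SOMModel"
))

setValidity("SOMSelection", function(object) {
  if (length(object@selected) > 2L * nrow(object@perNeuron))
    return("selected count exceeds 2 x occupied neurons")
  if (anyDuplicated(object@selected)) return("selected IDs must be unique")
  TRUE
})

#' Synthetic fullerene-derivative dataset
#'
#' Holds a generated descriptor matrix, a binding-score matrix, and the ground
#' truth (latents, protein cluster assignments, per-protein response weights)
#' sufficient to recompute the noiseless signal exactly. See
#' [generateDataset()].
#'
#' @slot descriptors compounds x descriptors numeric matrix.
#' @slot bindings compounds x proteins numeric matrix (Bscore units).
#' @slot latents list with elements `size`, `aromaticity` (per-compound
#'   latents), `proteinCluster`, `proteinOffset`, `proteinGain`.
#' @slot config the generating `SynthConfig` list (includes the seed).
#' @export
setClass("SynthDataset", representation(
  descriptors = "matrix", bindings = "matrix", latents = "list",
  config = "list"
))

setValidity("SynthDataset", function(object) {
  if (nrow(object@descriptors) != nrow(object@bindings))
    return("descriptors and bindings must have the same number of compounds")
  if (nrow(object@descriptors) != length(object@latents$size))
    return("size latent length must equal compound count")
  if (ncol(object@bindings) != length(object@latents$proteinCluster))
    return("proteinCluster length must equal protein count")
  TRUE
})

# internal: coerce to a positive scalar integer with a named error
.asCount <- function(x, what) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 1 || x != floor(x))
    stop(sprintf("'%s' must be a single positive integer", what), call. = FALSE)
  as.integer(x)
}
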