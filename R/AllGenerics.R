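#' Accessors for fdQSAR model and data classes
#'
#' Small accessor generics so user code never touches slots directly:
#' `somGrid()` and `somWeights()` expose the lattice and the weight matrix of
#' a [SOMModel-class] (or of the input layer of a [CPANNModel-class]),
#' `somConfig()` the training configuration, `isTrained()` the training flag,
#' `outputWeights()` the CPANN output layer, `selectedIds()` the deduplicated
#' selection of a [SOMSelection-class], and `descriptors()` / `bindings()` /
#' `trueLatents()` the components of a [SynthDataset-class].
#'
#' @param x an fdQSAR object of the appropriate class.
#' @return The slot value described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("somGrid", function(x) standardGeneric("somGrid"))
#' @rdname accessors
#' @export
setGeneric("somWeights", function(x) standardGeneric("somWeights"))
#' @rdname accessors
#' @export
setGeneric("somConfig", function(x) standardGeneric("somConfig"))
#' @rdname accessors
#' @export
setGeneric("isTrained", function(x) standardGeneric("isTrained"))
#' @rdname accessors
#' @export
setGeneric("outputWeights", function(x) standardGeneric("outputWeights"))
#' @rdname accessors
#' @export
setGeneric("selectedIds", function(x) standardGeneric("selectedIds"))
#' @rdname accessors
#' @export
setGeneric("descriptors", function(x) standardGeneric("descriptors"))
#' @rdname accessors
#' @export
setGeneric("bindings", function(x) standardGeneric("bindings"))
#' @rdname accessors
#' @export
setGeneric("trueLatents", function(x) standardGeneric("trueLatents"))

#' @rdname accessors
setMethod("somGrid", "SOMModel", function(x) x@grid)
#' @rdname accessors
setMethod("somGrid", "CPANNModel", function(x) x@som@grid)
#' @rdname accessors
setMethod("somWeights", "SOMModel", function(x) x@weights)
#' @rdname accessors
setMethod("somWeights", "CPANNModel", function(x) x@som@weights)
#' @rdname accessors
setMethod("somConfig", "SOMModel", function(x) x@config)
#' @rdname accessors
setMethod("somConfig", "CPANNModel", function(x) x@som@config)
#' @rdname accessors
setMethod("isTrained", "SOMModel", function(x) x@trained)
#' @rdname accessors
setMethod("isTrained", "CPANNModel", function(x) x@som@trained)
#' @rdname accessors
setMethod("outputWeights", "CPANNModel", function(x) x@outputWeights)
#' @rdname accessors
setMethod("selectedIds", "SOMSelection", function(x) x@selected)
#' @rdname accessors
setMethod("descriptors", "SynthDataset", function(x) x@descriptors)
#' @rdname accessors
setMethod("bindings", "SynthDataset", function(x) x@bindings)
#' @rdname accessors
setMethod("trueLatents", "SynthDataset", function(x) x@latents)

#' @describeIn GridSpec-class grid dimensions as `c(nx, ny)`.
#' @param x a `GridSpec`.
#' @export
setMethod("dim", "GridSpec", function(x) c(x@nx, x@ny))

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d planar Kohonen grid (%d neurons)\n",
              object@nx, object@ny, object@nx * object@ny))
})

setMethod("show", "TrainConfig", function(object) {
  rs <- if (is.na(object@radiusStart)) "auto (max(nx,ny)-1)"
        else format(object@radiusStart)
  cat("TrainConfig\n",
      sprintf("  epochs: %d\n", object@epochs),
      sprintf("  eta: %.3g -> %.3g (linear)\n", object@etaStart, object@etaEnd),
      sprintf("  radius: %s -> %s (linear)\n", rs, format(object@radiusEnd)),
      sprintf("  seed: %d\n", object@seed), sep = "")
})

setMethod("show", "SOMModel", function(object) {
  cat(sprintf("SOMModel: %d x %d map, %d features%s\n",
              object@grid@nx, object@grid@ny, ncol(object@weights),
              if (object@trained) " (trained)" else " (untrained)"))
  cat(sprintf("  epochs: %d, seed: %d\n",
              object@config@epochs, object@config@seed))
})

setMethod("show", "CPANNModel", function(object) {
  cat(sprintf("CPANNModel: %d x %d map, %d descriptors -> %d target(s)\n",
              object@som@grid@nx, object@som@grid@ny,
              ncol(object@som@weights), ncol(object@outputWeights)))
  cat(sprintf("  targets: %s\n", paste(object@targetNames, collapse = ", ")))
})

setMethod("show", "SOMSelection", function(object) {
  cat(sprintf(
    "SOMSelection: %d objects on a %d x %d map, %d occupied neurons, %d selected\n",
    nrow(object@mapping), object@model@grid@nx, object@model@grid@ny,
    nrow(object@perNeuron), length(object@selected)))
})

setMethod("show", "SynthDataset", function(object) {
  cat(sprintf(
    "SynthDataset: %d compounds, %d descriptors, %d proteins (%d clusters), seed %d\n",
    nrow(object@descriptors), ncol(object@descriptors), ncol(object@bindings),
    length(unique(object@latents$proteinCluster)), object@config$seed))
})
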