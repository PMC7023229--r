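# Fullerene-derivative analysis procedures: binding-score averaging, SOM
# reduction/selection, deltas against a reference compound, activity sectors
# and saturation labels.

#' Per-compound average binding score ("Average sum")
#'
#' Arithmetic mean of each compound's binding scores across all proteins in
#' the panel; the quantity used throughout the package as the binding
#' activity ("Av Bscores") of a compound.
#'
#' @param B numeric binding matrix, compounds x proteins, finite, no missing
#'   cells; rownames are compound IDs.
#' @return Named numeric vector of per-compound means.
#' @examples
#' B <- matrix(c(4000, 5000, 6000, 8000), 2, byrow = TRUE,
#'             dimnames = list(c("FD1", "FD2"), c("p1", "p2")))
#' averageBscores(B)
#' @export
averageBscores <- function(B) {
  B <- .asNumericMatrix(B)
  if (nrow(B) < 1L || ncol(B) < 1L) stop("binding matrix must be non-empty")
  av <- rowMeans(B)
  names(av) <- rownames(B) %||% paste0("FD", seq_len(nrow(B)))
  av
}

#' Average binding score over the top-k proteins
#'
#' Proteins are ranked by their mean binding score across all compounds
#' (descending; ties broken by protein ID in lexicographic order) and the
#' per-compound mean over the top `k` is returned. With `k = 110` this is
#' the "Average110" statistic.
#'
#' @param B binding matrix as in [averageBscores()].
#' @param k number of proteins to keep, `1 <= k <= ncol(B)`.
#' @return List with `proteins` (selected protein IDs, rank order) and
#'   `average` (named per-compound means over the selection).
#' @export
topKProteinAverage <- function(B, k) {
  B <- .asNumericMatrix(B)
  k <- .asCount(k, "k")
  if (k > ncol(B)) stop(sprintf("k = %d exceeds the %d proteins", k, ncol(B)))
  ids <- colnames(B) %||% paste0("p", seq_len(ncol(B)))
  pm <- colMeans(B)
  sel <- ids[order(-pm, ids)][seq_len(k)]
  avg <- rowMeans(B[, match(sel, ids), drop = FALSE])
  names(avg) <- rownames(B) %||% paste0("FD", seq_len(nrow(B)))
  list(proteins = sel, average = avg)
}

#' Reduce a set of objects by per-neuron min/max SOM selection
#'
#' Trains a Kohonen map on the (column-normalized) profiles, maps every
#' object, and keeps, per occupied neuron, the member with the smallest and
#' the member with the largest Euclidean distance to the neuron weight
#' vector. A single-member neuron contributes that member once; the
#' deduplicated union is the selection, so at most `2 x occupied neurons`
#' objects survive. Distance ties are broken by object ID order. This is the
#' procedure used both to reduce the protein panel (objects = proteins,
#' features = per-compound binding scores) and, via [selectDescriptors()],
#' to pick descriptors.
#'
#' @param profiles numeric matrix, objects x features; rownames are object
#'   IDs.
#' @param grid a [GridSpec-class] (a 5 x 5 map for the protein panel).
#' @param config a [TrainConfig-class].
#' @param normalize min-max normalize the profile columns first (default
#'   `TRUE`); set `FALSE` if `profiles` is already in `[0, 1]`.
#' @return A [SOMSelection-class].
#' @export
reduceBySOM <- function(profiles, grid, config = trainConfig(),
                        normalize = TRUE) {
  profiles <- .asNumericMatrix(profiles)
  if (nrow(profiles) < 1L) stop("'profiles' must contain at least one object")
  if (is.null(rownames(profiles)))
    rownames(profiles) <- paste0("obj", seq_len(nrow(profiles)))
  norm <- if (normalize) normalizeColumns(profiles)$data else profiles
  model <- trainSOM(norm, grid, config)
  mapping <- mapObjects(model, norm)
  perNeuron <- do.call(rbind, lapply(
    split(mapping, mapping$index), function(g) {
      g <- g[order(g$distance, g$id), , drop = FALSE]
      data.frame(row = g$row[1L], col = g$col[1L], n = nrow(g),
                 minId = g$id[1L], minDistance = g$distance[1L],
                 maxId = g$id[nrow(g)], maxDistance = g$distance[nrow(g)],
                 stringsAsFactors = FALSE)
    }))
  perNeuron <- perNeuron[order((perNeuron$row - 1L) * grid@ny + perNeuron$col), ,
                         drop = FALSE]
  rownames(perNeuron) <- NULL
  selected <- unique(as.vector(t(cbind(perNeuron$minId, perNeuron$maxId))))
  new("SOMSelection", mapping = mapping, perNeuron = perNeuron,
      selected = selected, model = model)
}

#' Select descriptors with a small Kohonen map
#'
#' Transposes the compounds x descriptors table so that descriptors become
#' the objects (each described by its values over all compounds) and applies
#' [reduceBySOM()] on a 2 x 2 map: per occupied neuron the nearest and
#' farthest descriptor are kept, yielding at most 8 descriptor names.
#'
#' @param X numeric matrix, compounds x descriptors, with descriptor column
#'   names.
#' @param grid a [GridSpec-class], default 2 x 2.
#' @param config a [TrainConfig-class].
#' @param normalize passed to [reduceBySOM()] (normalization is then per
#'   compound, i.e. per column of the transposed table).
#' @return Character vector of selected descriptor names (at most
#'   `2 * nx * ny`), with the full [SOMSelection-class] attached as attribute
#'   `"selection"`.
#' @export
selectDescriptors <- function(X, grid = gridSpec(2, 2),
                              config = trainConfig(), normalize = TRUE) {
  X <- .asNumericMatrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("d", seq_len(ncol(X)))
  if (ncol(X) < grid@nx * grid@ny)
    stop(sprintf("need at least %d descriptors for a %d x %d map",
                 grid@nx * grid@ny, grid@nx, grid@ny))
  sel <- reduceBySOM(t(X), grid, config, normalize = normalize)
  structure(selectedIds(sel), selection = sel)
}

#' Merge selected descriptors with mandatory extras
#'
#' Ordered union of a selected descriptor set and a fixed pair of
#' size-related descriptors (polarizability `QPpolrz` and topological
#' diameter `TD` by default), duplicates removed and extras appended last.
#' Eight SOM-selected descriptors plus the two extras give the 10-descriptor
#' consensus feature set.
#'
#' @param selected character vector of selected descriptor names.
#' @param extras character vector of descriptors to append (default
#'   `c("QPpolrz", "TD")`).
#' @param available optional character vector (or descriptor matrix column
#'   names) against which the extras are validated.
#' @return Character vector of feature names.
#' @examples
#' consensusFeatureSet(c("cLogS", "sp3_atoms"), c("QPpolrz", "TD"))
#' @export
consensusFeatureSet <- function(selected, extras = c("QPpolrz", "TD"),
                                available = NULL) {
  if (!is.null(available)) {
    if (is.matrix(available)) available <- colnames(available)
    missing <- setdiff(extras, available)
    if (length(missing))
      stop(sprintf("extra descriptor(s) not in table: %s",
                   paste(missing, collapse = ", ")))
  }
  c(setdiff(unique(selected), extras), extras)
}

#' Binding-activity difference against a reference compound
#'
#' `delta(fd) = av(fd) - av(ref)`; the reference (pristine C60 in the study
#' data) maps to 0. Adding a constant to every score leaves all deltas
#' unchanged.
#'
#' @param av named numeric vector of per-compound average binding scores.
#' @param refId name of the reference compound (must be present in `av`).
#' @return Named numeric vector of deltas, same order as `av`.
#' @examples
#' deltaVsReference(c(FD50 = 4224.3, FD168 = 3938.3), "FD168")
#' @export
deltaVsReference <- function(av, refId) {
  if (is.null(names(av))) stop("'av' must be a named vector of compound scores")
  if (!refId %in% names(av))
    stop(sprintf("reference compound '%s' not found in the score vector", refId))
  av - av[[refId]]
}

#' Classify compounds into binding-activity sectors
#'
#' Three-bin classification of average binding scores: scores above
#' `activeFloor` (5500) are "active" (sector 1), scores in
#' `(moderateFloor, activeFloor]` are "moderate" (sector 2), and scores at or
#' below `moderateFloor` (5000) are "low" (sector 3, unbounded below).
#' Boundaries are upper-exclusive: a score of exactly 5500 is moderate and
#' 5000 is low. `upperActive` and `lowFloor` describe the nominal score range
#' (8000 and 4000) but do not affect the label.
#'
#' @param score numeric vector of average binding scores (finite).
#' @param thresholds named list/vector with `activeFloor` and `moderateFloor`
#'   (and optionally the descriptive `upperActive`, `lowFloor`); thresholds
#'   must be strictly decreasing.
#' @return Ordered factor with levels `low < moderate < active`.
#' @examples
#' classifyActivity(c(6000, 5200, 3938.3))
#' @export
classifyActivity <- function(score,
                             thresholds = list(upperActive = 8000,
                                               activeFloor = 5500,
                                               moderateFloor = 5000,
                                               lowFloor = 4000)) {
  if (any(!is.finite(score))) stop("scores must be finite")
  af <- thresholds$activeFloor %||% 5500
  mf <- thresholds$moderateFloor %||% 5000
  if (!(af > mf)) stop("thresholds must be strictly decreasing")
  lab <- ifelse(score > af, "active", ifelse(score > mf, "moderate", "low"))
  factor(lab, levels = c("low", "moderate", "active"), ordered = TRUE)
}

#' Classify compounds as saturated or unsaturated
#'
#' Saturation (hydrogenation level) is decided from the sp3-atom count alone:
#' zero sp3 atoms means unsaturated (pristine C60/C70 cages), a count above
#' `saturatedThreshold` (60) means saturated, and anything in between is
#' "ambiguous" — only the outer limits separate cleanly. Stereo-center
#' counts, though strongly correlated with sp3 atoms, are accepted for
#' reporting but do not influence the label.
#'
#' @param sp3Atoms non-negative integer vector of sp3-hybridized atom counts.
#' @param stereoCenters optional non-negative counts, validated but unused.
#' @param saturatedThreshold sp3 count above which a compound is saturated
#'   (default 60).
#' @return Factor with levels `unsaturated`, `ambiguous`, `saturated`.
#' @examples
#' classifySaturation(c(0, 30, 70))
#' @export
classifySaturation <- function(sp3Atoms, stereoCenters = NULL,
                               saturatedThreshold = 60) {
  if (any(!is.finite(sp3Atoms)) || any(sp3Atoms < 0))
    stop("sp3 atom counts must be non-negative")
  if (!is.null(stereoCenters) && any(stereoCenters < 0))
    stop("stereo-center counts must be non-negative")
  lab <- ifelse(sp3Atoms == 0, "unsaturated",
                ifelse(sp3Atoms > saturatedThreshold, "saturated", "ambiguous"))
  factor(lab, levels = c("unsaturated", "ambiguous", "saturated"))
}
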