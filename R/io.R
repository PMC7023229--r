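# Readers/writers and the end-to-end analysis pipeline.

.sepForPath <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a delimited numeric matrix with IDs
#'
#' TSV by default, CSV auto-detected from the `.csv` extension (explicit
#' `sep` overrides). The first row holds column names and the first column
#' object IDs; decimals use the dot separator (a comma-decimal cell is an
#' error with advice, never locale-guessed). Duplicate IDs, ragged rows and
#' non-numeric cells are reported with their location.
#'
#' @param path file path.
#' @param sep field separator override (`"\t"` or `","`).
#' @return Numeric matrix with row and column names.
#' @seealso [writeMatrix()]
#' @export
readMatrix <- function(path, sep = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  sep <- .sepForPath(path, sep)
  raw <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, quote = "",
                      colClasses = "character", check.names = FALSE,
                      comment.char = "", stringsAsFactors = FALSE),
    error = function(e) stop(sprintf("cannot parse '%s': %s", path,
                                     conditionMessage(e)), call. = FALSE))
  if (ncol(raw) < 2L) stop(sprintf("'%s' needs an ID column plus data", path))
  ids <- raw[[1L]]
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop(sprintf("duplicated object ID(s) in '%s': %s", path,
                 paste(unique(dup), collapse = ", ")))
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  commaDec <- grepl("^-?[0-9]+,[0-9]+$", vals)
  if (any(commaDec)) {
    bad <- which(matrix(commaDec, nrow(vals)), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "comma decimal separator at row '%s', column '%s'; use dot-decimal numbers",
      ids[bad[1L]], colnames(vals)[bad[2L]]))
  }
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals),
                                 dimnames = list(ids, colnames(vals))))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric value '%s' at row '%s', column '%s' of '%s'",
                 vals[bad[1L], bad[2L]], ids[bad[1L]],
                 colnames(num)[bad[2L]], path))
  }
  num
}

#' Write a numeric matrix with IDs
#'
#' @param x numeric matrix with dimnames.
#' @param path output path; `.csv` switches to comma separation.
#' @param sep separator override.
#' @param idHeader header of the ID column (default `"id"`).
#' @export
writeMatrix <- function(x, path, sep = NULL, idHeader = "id") {
  sep <- .sepForPath(path, sep)
  x <- .asNumericMatrix(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("obj", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("v", seq_len(ncol(x)))
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- idHeader
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- model persistence ----------------------------------------------------
# Plain-text format with %.17g numbers, guaranteeing exact double round-trip.

.fmtNum <- function(x) sprintf("%.17g", x)

.writeConfigLines <- function(config) {
  c(sprintf("epochs %d", config@epochs),
    sprintf("etaStart %s", .fmtNum(config@etaStart)),
    sprintf("etaEnd %s", .fmtNum(config@etaEnd)),
    sprintf("radiusStart %s", .fmtNum(config@radiusStart)),
    sprintf("radiusEnd %s", .fmtNum(config@radiusEnd)),
    sprintf("seed %d", config@seed))
}

.parseConfigLines <- function(kv) {
  trainConfig(epochs = as.integer(kv[["epochs"]]),
              etaStart = as.numeric(kv[["etaStart"]]),
              etaEnd = as.numeric(kv[["etaEnd"]]),
              radiusStart = as.numeric(kv[["radiusStart"]]),
              radiusEnd = as.numeric(kv[["radiusEnd"]]),
              seed = as.integer(kv[["seed"]]))
}

.weightLines <- function(W) {
  apply(W, 1L, function(r) paste(.fmtNum(r), collapse = "\t"))
}

.parseWeightLines <- function(lines, nrow, ncol) {
  vals <- as.numeric(unlist(strsplit(lines, "\t", fixed = TRUE)))
  matrix(vals, nrow = nrow, ncol = ncol, byrow = TRUE)
}

#' Save / load a trained SOM as structured text
#'
#' The file records grid, training configuration, seed, feature names and
#' weights at full double precision (`%.17g`), so a read-back model is
#' bit-identical to the saved one.
#'
#' @param model a [SOMModel-class].
#' @param path file path.
#' @return `writeSOMModel` returns `path` invisibly; `readSOMModel` returns
#'   the restored [SOMModel-class].
#' @export
writeSOMModel <- function(model, path) {
  stopifnot(is(model, "SOMModel"))
  lines <- c("fdQSAR-SOMModel v1",
             sprintf("nx %d", model@grid@nx),
             sprintf("ny %d", model@grid@ny),
             .writeConfigLines(model@config),
             sprintf("trained %s", model@trained),
             paste0("features ", paste(model@featureNames, collapse = "\t")),
             sprintf("weights %d %d", nrow(model@weights), ncol(model@weights)),
             .weightLines(model@weights))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeSOMModel
#' @export
readSOMModel <- function(path) {
  lines <- readLines(path)
  if (lines[1L] != "fdQSAR-SOMModel v1")
    stop(sprintf("'%s' is not an fdQSAR SOM model file", path))
  .parseSOMLines(lines[-1L])$model
}

.parseSOMLines <- function(lines) {
  kv <- list()
  i <- 1L
  while (!startsWith(lines[i], "weights ")) {
    sp <- regmatches(lines[i], regexpr(" ", lines[i]), invert = TRUE)[[1L]]
    kv[[sp[1L]]] <- sp[2L]
    i <- i + 1L
  }
  dims <- as.integer(strsplit(lines[i], " ")[[1L]][2:3])
  W <- .parseWeightLines(lines[(i + 1L):(i + dims[1L])], dims[1L], dims[2L])
  model <- new("SOMModel",
               grid = gridSpec(as.integer(kv$nx), as.integer(kv$ny)),
               weights = W,
               featureNames = strsplit(kv$features, "\t", fixed = TRUE)[[1L]],
               config = .parseConfigLines(kv),
               trained = as.logical(kv$trained))
  list(model = model, consumed = 1L + i + dims[1L])
}

#' Save / load a trained CPANN as structured text
#'
#' @param model a [CPANNModel-class].
#' @param path file path.
#' @return `writeCPANNModel` returns `path` invisibly; `readCPANNModel`
#'   returns the restored [CPANNModel-class] (bit-identical weights).
#' @export
writeCPANNModel <- function(model, path) {
  stopifnot(is(model, "CPANNModel"))
  sc <- model@targetScale$scale
  scLines <- if (is.null(sc)) "targetScale 0" else c(
    sprintf("targetScale %d", nrow(sc)),
    sprintf("%s\t%s\t%s\t%s", sc$feature, .fmtNum(sc$min), .fmtNum(sc$max),
            sc$constant))
  lines <- c("fdQSAR-CPANNModel v1",
             sprintf("nx %d", model@som@grid@nx),
             sprintf("ny %d", model@som@grid@ny),
             .writeConfigLines(model@som@config),
             sprintf("trained %s", model@som@trained),
             paste0("features ", paste(model@som@featureNames, collapse = "\t")),
             sprintf("weights %d %d", nrow(model@som@weights),
                     ncol(model@som@weights)),
             .weightLines(model@som@weights),
             paste0("targets ", paste(model@targetNames, collapse = "\t")),
             sprintf("outputWeights %d %d", nrow(model@outputWeights),
                     ncol(model@outputWeights)),
             .weightLines(model@outputWeights),
             scLines)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeCPANNModel
#' @export
readCPANNModel <- function(path) {
  lines <- readLines(path)
  if (lines[1L] != "fdQSAR-CPANNModel v1")
    stop(sprintf("'%s' is not an fdQSAR CPANN model file", path))
  body <- lines[-1L]
  somPart <- .parseSOMLines(body)
  rest <- body[(somPart$consumed):length(body)]
  targets <- strsplit(sub("^targets ", "", rest[1L]), "\t", fixed = TRUE)[[1L]]
  dims <- as.integer(strsplit(rest[2L], " ")[[1L]][2:3])
  Wy <- .parseWeightLines(rest[3:(2L + dims[1L])], dims[1L], dims[2L])
  scHead <- rest[3L + dims[1L]]
  nsc <- as.integer(strsplit(scHead, " ")[[1L]][2L])
  targetScale <- list()
  if (nsc > 0L) {
    scRows <- rest[(4L + dims[1L]):(3L + dims[1L] + nsc)]
    parts <- do.call(rbind, strsplit(scRows, "\t", fixed = TRUE))
    targetScale <- list(scale = data.frame(
      feature = parts[, 1L], min = as.numeric(parts[, 2L]),
      max = as.numeric(parts[, 3L]), constant = as.logical(parts[, 4L]),
      stringsAsFactors = FALSE))
  }
  new("CPANNModel", som = somPart$model, outputWeights = Wy,
      targetNames = targets, targetScale = targetScale)
}

# ---- pipeline -------------------------------------------------------------

# per-stage seed: deterministic hash of the stage name folded into the master
# seed, so stage reordering cannot silently change results
.stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  .deriveSeed(seed, h)
}

#' Run the full fullerene-derivative analysis pipeline
#'
#' Chains the analysis stages on a descriptor table and a binding matrix:
#' per-compound average binding scores; SOM reduction of the protein panel
#' (5 x 5 map); top-k protein averages (k = 110); the correlation table of
#' the three averages with the size descriptors; 2 x 2 SOM descriptor
#' selection and the consensus feature set; CPANN models on all descriptors
#' and on the consensus set, each with optional leave-one-out
#' cross-validation; activity-sector, saturation and delta-vs-reference
#' reports; and a heatmap export of the binding matrix ordered by activity.
#' Every artifact is written as TSV into `outDir` together with a
#' configuration echo and a timing log. Identical inputs, settings and seed
#' give byte-identical numeric artifacts.
#'
#' @param descriptors compounds x descriptors matrix, or a file path readable
#'   by [readMatrix()].
#' @param bindings compounds x proteins binding matrix, or a file path.
#' @param outDir output directory (created if needed).
#' @param proteinGrid,modelGrid,descriptorGrid grid sizes `c(nx, ny)` for the
#'   protein-reduction, regression and descriptor-selection maps (defaults
#'   5x5, 20x20, 2x2).
#' @param topK number of top proteins to average (default 110).
#' @param epochs learning epochs for every map (default 100).
#' @param extras descriptors appended to the consensus set (default
#'   `c("QPpolrz", "TD")`; silently skipped if absent from the table).
#' @param referenceId optional reference compound for delta reporting; if
#'   given it must exist in the binding matrix.
#' @param ccThreshold reporting threshold for high correlations (default 0.6).
#' @param sp3Column,sp3Threshold descriptor column and limit for the
#'   saturation report (defaults `"sp3_atoms"`, 60).
#' @param seed master seed; per-stage seeds are derived from it by stage
#'   name.
#' @param loo run leave-one-out cross-validation for both models (default
#'   `TRUE`; the dominant computational cost).
#' @return Invisibly, a list with the computed objects (`averages`,
#'   `proteinSelection`, `correlations`, `selectedDescriptors`,
#'   `consensusSet`, `model27`, `model10`, fit/CV metrics, `artifacts`).
#' @export
runPipeline <- function(descriptors, bindings, outDir,
                        proteinGrid = c(5, 5), modelGrid = c(20, 20),
                        descriptorGrid = c(2, 2), topK = 110, epochs = 100,
                        extras = c("QPpolrz", "TD"), referenceId = NULL,
                        ccThreshold = 0.6, sp3Column = "sp3_atoms",
                        sp3Threshold = 60, seed = 1L, loo = TRUE) {
  if (!dir.exists(outDir) && !dir.create(outDir, recursive = TRUE))
    stop(sprintf("cannot create output directory '%s'", outDir))
  logFile <- file.path(outDir, "run_log.txt")
  cat(sprintf("fdQSAR pipeline, seed %d, started %s\n", seed,
              format(Sys.time())), file = logFile)
  artifacts <- character()
  t0 <- proc.time()[["elapsed"]]
  logStage <- function(name) {
    msg <- sprintf("[%7.2fs] %s", proc.time()[["elapsed"]] - t0, name)
    message(msg)
    cat(msg, "\n", file = logFile, append = TRUE)
  }
  stage <- function(name, expr) {
    logStage(name)
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  emit <- function(name, writer) {
    path <- file.path(outDir, name)
    writer(path)
    artifacts <<- c(artifacts, path)
    path
  }

  X <- stage("read_descriptors",
             if (is.character(descriptors)) readMatrix(descriptors)
             else .asNumericMatrix(descriptors))
  B <- stage("read_bindings",
             if (is.character(bindings)) readMatrix(bindings)
             else .asNumericMatrix(bindings))
  if (nrow(X) != nrow(B) || !identical(rownames(X), rownames(B)))
    stop("descriptor and binding matrices must share the same compound rows")

  if (!is.null(referenceId) && !referenceId %in% rownames(B))
    stop(sprintf(
      "stage 'delta_vs_reference' failed: reference compound '%s' not in the binding matrix",
      referenceId))

  av <- stage("average_bscores", averageBscores(B))

  psel <- stage("reduce_proteins_som", reduceBySOM(
    t(B), gridSpec(proteinGrid[1L], proteinGrid[2L]),
    trainConfig(epochs = epochs, seed = .stageSeed(seed, "reduce_proteins"))))
  avSelected <- rowMeans(B[, selectedIds(psel), drop = FALSE])
  emit("02_protein_selection.tsv", function(p)
    utils::write.table(psel@perNeuron, p, sep = "\t", quote = FALSE,
                       row.names = FALSE))

  k <- min(topK, ncol(B))
  topk <- stage("top_k_protein_average", topKProteinAverage(B, k))
  emit("03_topk_proteins.tsv", function(p)
    utils::write.table(
      data.frame(rank = seq_along(topk$proteins), protein = topk$proteins),
      p, sep = "\t", quote = FALSE, row.names = FALSE))

  activityTab <- cbind(average_sum = av, average_topk = topk$average,
                       average_selected = avSelected)
  extrasPresent <- intersect(extras, colnames(X))
  corTab <- cbind(activityTab, X[, extrasPresent, drop = FALSE])
  cors <- stage("correlation_table", correlationMatrix(corTab))
  emit("04_correlation_table.tsv", function(p)
    writeMatrix(signif(cors, 6), p, idHeader = "variable"))
  pairs <- highCCPairs(correlationMatrix(X), threshold = ccThreshold)
  emit("05_high_cc_pairs.tsv", function(p)
    utils::write.table(transform(pairs, cc = signif(cc, 6)), p, sep = "\t",
                       quote = FALSE, row.names = FALSE))

  # the SOM selection runs on the drug-like descriptors only; the size
  # descriptors in `extras` are appended afterwards by the consensus step
  drugLike <- setdiff(colnames(X), extrasPresent)
  selNames <- stage("select_descriptors", selectDescriptors(
    X[, drugLike, drop = FALSE],
    gridSpec(descriptorGrid[1L], descriptorGrid[2L]),
    trainConfig(epochs = epochs,
                seed = .stageSeed(seed, "select_descriptors"))))
  consensus <- stage("consensus_feature_set",
                     consensusFeatureSet(selNames, extrasPresent,
                                         available = colnames(X)))
  emit("06_selected_descriptors.tsv", function(p)
    utils::write.table(
      data.frame(descriptor = consensus,
                 source = c(rep("som", length(consensus) - length(extrasPresent)),
                            rep("extra", length(extrasPresent)))),
      p, sep = "\t", quote = FALSE, row.names = FALSE))

  normX <- normalizeColumns(X)
  normY <- normalizeColumns(matrix(av, ncol = 1L,
                                   dimnames = list(names(av), "avBscore")))
  fitModel <- function(cols, label) {
    cfg <- trainConfig(epochs = epochs,
                       seed = .stageSeed(seed, paste0("cpann_", label)))
    Xm <- normX$data[, cols, drop = FALSE]
    model <- trainCPANN(Xm, normY$data[, 1L], gridSpec(modelGrid[1L],
                                                       modelGrid[2L]),
                        cfg, targetScale = normY$scale)
    fm <- fitMetrics(normY$data[, 1L], predict(model, Xm))
    cv <- if (loo) looCV(normX$data[, cols, drop = FALSE], normY$data[, 1L],
                         gridSpec(modelGrid[1L], modelGrid[2L]), cfg)
          else NULL
    list(model = model, fit = fm, cv = cv)
  }
  m27 <- stage("cpann_all_descriptors", fitModel(colnames(X), "all"))
  m10 <- stage("cpann_consensus", fitModel(consensus, "consensus"))
  summary <- data.frame(
    model = c("all_descriptors", "consensus"),
    nDescriptors = c(ncol(X), length(consensus)),
    r2 = signif(c(m27$fit$r2, m10$fit$r2), 6),
    rmse = signif(c(m27$fit$rmse, m10$fit$rmse), 6),
    q2cv = if (loo) signif(c(m27$cv$q2cv, m10$cv$q2cv), 6) else NA,
    rmsecv = if (loo) signif(c(m27$cv$rmsecv, m10$cv$rmsecv), 6) else NA)
  emit("07_model_summary.tsv", function(p)
    utils::write.table(summary, p, sep = "\t", quote = FALSE,
                       row.names = FALSE))
  predTab <- data.frame(
    id = names(av), observed = signif(av, 6),
    predicted_all = signif(denormalizeColumns(
      matrix(predict(m27$model, normX$data), ncol = 1L), normY$scale)[, 1L], 6),
    predicted_consensus = signif(denormalizeColumns(
      matrix(predict(m10$model, normX$data[, consensus, drop = FALSE]),
             ncol = 1L), normY$scale)[, 1L], 6))
  emit("08_model_predictions.tsv", function(p)
    utils::write.table(predTab, p, sep = "\t", quote = FALSE,
                       row.names = FALSE))

  report <- stage("compound_report", {
    rep <- data.frame(id = names(av), avBscore = signif(av, 6),
                      activity = as.character(classifyActivity(av)))
    if (!is.null(referenceId))
      rep$deltaVsReference <- signif(deltaVsReference(av, referenceId), 6)
    if (sp3Column %in% colnames(X))
      rep$saturation <- as.character(
        classifySaturation(X[, sp3Column],
                           saturatedThreshold = sp3Threshold))
    rep
  })
  emit("09_compound_report.tsv", function(p)
    utils::write.table(report, p, sep = "\t", quote = FALSE,
                       row.names = FALSE))

  stage("heatmap_export", {
    ord <- order(-av)
    rng <- range(av)
    bins <- cut(av, breaks = seq(rng[1L], rng[2L], length.out = 4L),
                labels = c("low", "moderate", "high"), include.lowest = TRUE)
    hm <- data.frame(id = names(av)[ord], avBscore = signif(av[ord], 6),
                     bin = as.character(bins)[ord],
                     signif(B[ord, , drop = FALSE], 6), check.names = FALSE)
    emit("10_heatmap.tsv", function(p)
      utils::write.table(hm, p, sep = "\t", quote = FALSE, row.names = FALSE))
  })

  emit("01_average_bscores.tsv", function(p)
    utils::write.table(
      data.frame(id = names(av), avBscore = signif(av, 6)),
      p, sep = "\t", quote = FALSE, row.names = FALSE))

  cfgEcho <- c(sprintf("seed %d", seed),
               sprintf("proteinGrid %s", paste(proteinGrid, collapse = "x")),
               sprintf("modelGrid %s", paste(modelGrid, collapse = "x")),
               sprintf("descriptorGrid %s",
                       paste(descriptorGrid, collapse = "x")),
               sprintf("topK %d", k), sprintf("epochs %d", epochs),
               sprintf("ccThreshold %g", ccThreshold),
               sprintf("sp3Threshold %g", sp3Threshold),
               sprintf("referenceId %s", referenceId %||% "none"),
               sprintf("loo %s", loo))
  writeLines(cfgEcho, file.path(outDir, "run_config.txt"))
  logStage("done")

  invisible(list(
    averages = activityTab, proteinSelection = psel, correlations = cors,
    highCC = pairs, selectedDescriptors = selNames, consensusSet = consensus,
    model27 = m27, model10 = m10, report = report, artifacts = artifacts))
}
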