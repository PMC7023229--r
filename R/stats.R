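# Correlation analysis and PCA loadings for descriptor tables.

#' Pearson product-moment correlation
#'
#' Thin wrapper over the standard estimator with the input checks the
#' pipeline relies on: equal lengths of at least 3, finite values, neither
#' vector constant.
#'
#' @param x,y numeric vectors.
#' @return Correlation coefficient in `[-1, 1]`.
#' @examples
#' pearsonCC(1:4, c(2, 1, 4, 3))
#' @export
pearsonCC <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  stats::cor(x, y)
}

#' Pairwise Pearson correlation matrix
#'
#' Computes all pairwise correlations of the columns of a table. Constant
#' columns (correlation undefined) are dropped with a warning rather than
#' aborting the analysis.
#'
#' @param table numeric matrix or data.frame, objects x variables, >= 3
#'   rows.
#' @return Symmetric numeric matrix with unit diagonal and entries in
#'   `[-1, 1]`, dimnames the retained variable names.
#' @export
correlationMatrix <- function(table) {
  x <- .asNumericMatrix(table)
  if (nrow(x) < 3L) stop("need at least 3 objects")
  if (is.null(colnames(x))) colnames(x) <- paste0("v", seq_len(ncol(x)))
  const <- apply(x, 2L, function(col) max(col) == min(col))
  if (any(const)) {
    warning(sprintf("dropping constant column(s): %s",
                    paste(colnames(x)[const], collapse = ", ")))
    x <- x[, !const, drop = FALSE]
  }
  if (ncol(x) < 1L) stop("no non-constant columns left")
  cm <- stats::cor(x)
  # enforce exact symmetry and unit diagonal against round-off
  cm <- (cm + t(cm)) / 2
  diag(cm) <- 1
  cm
}

#' List highly correlated variable pairs
#'
#' All unordered off-diagonal pairs with `|cc| >= threshold`, each listed
#' once, sorted by decreasing `|cc|`.
#'
#' @param cm correlation matrix (as from [correlationMatrix()]).
#' @param threshold absolute-correlation cut-off in `(0, 1]` (default 0.6,
#'   the conventional reporting cut for descriptor collinearity).
#' @return data.frame with columns `varA`, `varB`, `cc`.
#' @export
highCCPairs <- function(cm, threshold = 0.6) {
  if (length(threshold) != 1L || !is.finite(threshold) ||
      threshold <= 0 || threshold > 1)
    stop("'threshold' must lie in (0, 1]")
  if (!is.matrix(cm) || nrow(cm) != ncol(cm))
    stop("'cm' must be a square correlation matrix")
  vars <- colnames(cm) %||% paste0("v", seq_len(ncol(cm)))
  out <- data.frame(varA = character(), varB = character(), cc = numeric(),
                    stringsAsFactors = FALSE)
  p <- ncol(cm)
  if (p >= 2L) {
    idx <- which(upper.tri(cm) & abs(cm) >= threshold, arr.ind = TRUE)
    if (nrow(idx)) {
      out <- data.frame(varA = vars[idx[, 1L]], varB = vars[idx[, 2L]],
                        cc = cm[idx], stringsAsFactors = FALSE)
      out <- out[order(-abs(out$cc), out$varA, out$varB), , drop = FALSE]
      rownames(out) <- NULL
    }
  }
  out
}

#' Principal component loadings of a descriptor table
#'
#' Components are the eigenvectors of the correlation matrix of the table
#' (i.e. PCA on per-column standardized data; descriptor units are
#' incommensurable, so the correlation form is used), ordered by eigenvalue.
#' The sign of each component is fixed so that its largest-magnitude loading
#' is positive — eigenvector signs are otherwise arbitrary and would break
#' reproducibility. Constant columns are dropped with a warning.
#'
#' @param table numeric matrix or data.frame, objects x variables, >= 3
#'   rows.
#' @param nComponents number of components to return (default 2, the loading
#'   plot).
#' @param standardize use the correlation matrix (`TRUE`, default) or the
#'   covariance matrix.
#' @return List of class `fdPCA`: `loadings` (variables x components,
#'   orthonormal columns), `explainedVariance` (fractions of total variance,
#'   non-increasing), `scores` (objects x components), `dropped` (names of
#'   dropped constant columns).
#' @export
pcaLoadings <- function(table, nComponents = 2, standardize = TRUE) {
  x <- .asNumericMatrix(table)
  if (nrow(x) < 3L) stop("need at least 3 objects")
  if (is.null(colnames(x))) colnames(x) <- paste0("v", seq_len(ncol(x)))
  const <- apply(x, 2L, function(col) max(col) == min(col))
  dropped <- colnames(x)[const]
  if (any(const)) {
    warning(sprintf("dropping constant column(s): %s",
                    paste(dropped, collapse = ", ")))
    x <- x[, !const, drop = FALSE]
  }
  p <- ncol(x)
  nComponents <- .asCount(nComponents, "nComponents")
  if (nComponents > p)
    stop(sprintf("nComponents = %d exceeds the %d usable variables",
                 nComponents, p))
  C <- if (standardize) stats::cor(x) else stats::cov(x)
  ee <- eigen((C + t(C)) / 2, symmetric = TRUE)
  vals <- pmax(ee$values, 0)
  load <- ee$vectors[, seq_len(nComponents), drop = FALSE]
  for (j in seq_len(ncol(load))) {
    peak <- which.max(abs(load[, j]))
    if (load[peak, j] < 0) load[, j] <- -load[, j]
  }
  dimnames(load) <- list(colnames(x), paste0("PC", seq_len(nComponents)))
  centered <- scale(x, center = TRUE, scale = standardize)
  scores <- centered %*% load
  structure(list(
    loadings = load,
    explainedVariance = (vals / sum(vals))[seq_len(nComponents)],
    scores = scores, dropped = dropped), class = "fdPCA")
}

#' @export
print.fdPCA <- function(x, ...) {
  cat(sprintf("PCA loadings: %d variables, %d components\n",
              nrow(x$loadings), ncol(x$loadings)))
  cat("explained variance fractions:",
      paste(sprintf("%.3f", x$explainedVariance), collapse = ", "), "\n")
  invisible(x)
}
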