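#' @include AllClasses.R
NULL

#' Fit and apply z-score standardization
#'
#' Standardizes every row of a block as \eqn{X'_{ij} = (X_{ij} - \bar X_j)/S_j}
#' with the sample standard deviation (n-1 denominator). In
#' \code{"calibration"} mode (the default) the statistics \eqn{\bar X_j, S_j}
#' come exclusively from the calibration rows and are then applied to all
#' rows, so validation samples can never leak into the fitted scale. The
#' \code{"pooled"} mode fits the statistics on all rows jointly.
#'
#' @param block a \linkS4class{SourceBlock} or a numeric matrix with dimnames.
#' @param calibrationIds sample IDs of the calibration subset (>= 2 samples);
#'   ignored in pooled mode except for the subset check.
#' @param mode \code{"calibration"} or \code{"pooled"}.
#' @return A list with \code{params} (\linkS4class{StandardizationParams}) and
#'   \code{values} (the standardized matrix covering all rows).
#' @examples
#' m <- matrix(c(1, 2, 3, 10, 20, 30), 3, 2,
#'   dimnames = list(c("a", "b", "c"), c("f1", "f2")))
#' standardizeBlock(SourceBlock(m, "EN"), calibrationIds = c("a", "b", "c"))
#' @export
standardizeBlock <- function(block, calibrationIds,
    mode = c("calibration", "pooled")) {
  mode <- match.arg(mode)
  v <- if (methods::is(block, "SourceBlock")) featureValues(block) else block
  stopifnot(is.matrix(v), !is.null(rownames(v)))
  if (!all(calibrationIds %in% rownames(v)))
    stop("calibrationIds not all present in block", call. = FALSE)
  if (length(calibrationIds) < 2L)
    stop("calibration subset must have >= 2 samples", call. = FALSE)
  fitRows <- if (mode == "calibration") v[calibrationIds, , drop = FALSE] else v
  mu <- colMeans(fitRows)
  sdv <- apply(fitRows, 2L, stats::sd)
  zero <- sdv == 0
  if (any(zero))
    stop("zero-variance column(s) on the fitting rows: ",
      paste(colnames(v)[zero], collapse = ", "), call. = FALSE)
  params <- methods::new("StandardizationParams",
    means = stats::setNames(mu, colnames(v)),
    sds = stats::setNames(sdv, colnames(v)), mode = mode)
  list(params = params, values = applyStandardization(params, v))
}

#' Apply fitted standardization statistics to new rows
#'
#' @param params a \linkS4class{StandardizationParams}.
#' @param rows numeric matrix with the same columns the params were fitted on.
#' @return The standardized matrix.
#' @export
applyStandardization <- function(params, rows) {
  stopifnot(methods::is(params, "StandardizationParams"))
  if (ncol(rows) != length(params@means))
    stop("column-count mismatch with fitted standardization", call. = FALSE)
  sweep(sweep(rows, 2L, params@means, "-"), 2L, params@sds, "/")
}

#' SplitResult: calibration/validation partition
#'
#' @slot calibrationIds ordered calibration sample IDs (selection order).
#' @slot validationIds remaining sample IDs (input order).
#' @export
setClass("SplitResult",
  slots = c(calibrationIds = "character", validationIds = "character"))

setValidity("SplitResult", function(object) {
  if (length(intersect(object@calibrationIds, object@validationIds)))
    return("calibration and validation IDs must be disjoint")
  TRUE
})

setMethod("show", "SplitResult", function(object) {
  cat(sprintf("SplitResult: %d calibration / %d validation samples\n",
    length(object@calibrationIds), length(object@validationIds)))
})

#' Kennard-Stone calibration/validation partition
#'
#' Deterministic greedy max-min-distance selection: the pair with the largest
#' Euclidean distance is selected first, then the sample maximizing its
#' minimum distance to the already-selected set is added repeatedly until
#' \code{nCalibration} samples are chosen. Ties resolve to the lowest row
#' index, so the result is fully determined by the input order.
#'
#' The caller chooses the feature space; for multi-source data the
#' conventional choice is the z-scored concatenation of all blocks
#' (see [splitDataset()]).
#'
#' @param features n x p numeric matrix (rownames used as IDs when present).
#' @param nCalibration number of calibration samples, \code{2 <= nCalibration < n}.
#' @return A \linkS4class{SplitResult}.
#' @examples
#' x <- matrix(c(0, 1, 2, 10), dimnames = list(paste0("S", 1:4), "f"))
#' kennardStone(x, 2)
#' @export
kennardStone <- function(features, nCalibration) {
  n <- nrow(features)
  nCalibration <- as.integer(nCalibration)
  if (nCalibration < 2L || nCalibration >= n)
    stop("nCalibration must satisfy 2 <= nCalibration < n", call. = FALSE)
  ids <- rownames(features)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  D <- as.matrix(stats::dist(features))
  # initial pair: maximal distance, ties -> smallest (i, j) lexicographically
  best <- c(1L, 2L)
  bestD <- -Inf
  for (i in seq_len(n - 1L)) {
    j <- i + which.max(D[i, (i + 1L):n])
    if (D[i, j] > bestD) { bestD <- D[i, j]; best <- c(i, j) }
  }
  sel <- best
  minD <- pmin(D[, best[1L]], D[, best[2L]])
  minD[sel] <- -Inf
  while (length(sel) < nCalibration) {
    nxt <- which.max(minD)        # ties -> lowest row index
    sel <- c(sel, nxt)
    minD <- pmin(minD, D[, nxt])
    minD[nxt] <- -Inf
  }
  methods::new("SplitResult", calibrationIds = ids[sel],
    validationIds = ids[setdiff(seq_len(n), sel)])
}

#' Kennard-Stone split of a multi-source dataset
#'
#' Convenience wrapper: z-scores every block over all samples, concatenates
#' the blocks column-wise, and runs [kennardStone()] in that joint space.
#' (This pre-split scaling only defines the distance metric; model
#' standardization is refitted on calibration rows afterwards.)
#'
#' @param dataset a \linkS4class{MultiSourceDataset}.
#' @param nCalibration calibration-set size (e.g. 100 of 134).
#' @return A \linkS4class{SplitResult}.
#' @export
splitDataset <- function(dataset, nCalibration) {
  scaled <- lapply(blocks(dataset), function(b) {
    v <- featureValues(b)
    sdv <- apply(v, 2L, stats::sd)
    keep <- sdv > 0
    scale(v[, keep, drop = FALSE])
  })
  kennardStone(do.call(cbind, scaled), nCalibration)
}
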