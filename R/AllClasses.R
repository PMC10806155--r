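#' @include AllGenerics.R
NULL

# Central S4 data structures. All matrices are samples-in-rows with mandatory
# dimnames; validity methods enforce the structural invariants every other
# function relies on.

.UNASSIGNED <- "UNASSIGNED"

#' Label used for samples whose best score falls below the threshold
#'
#' Samples whose maximal class score is below a classifier's assignment
#' threshold are reported with this label rather than forced into a class;
#' they are tallied separately from misclassifications.
#'
#' @return The character constant \code{"UNASSIGNED"}.
#' @examples
#' unassignedLabel()
#' @export
unassignedLabel <- function() .UNASSIGNED

#' SourceBlock: one instrument's sample-by-feature matrix
#'
#' Holds the response matrix of a single data source (e.g. the 10 metal-oxide
#' sensors of an electronic nose, 85 colour values of an electronic eye,
#' 8 taste membranes of an electronic tongue, or HPLC peak areas), together
#' with sample identifiers (rownames) and feature names (colnames).
#'
#' @slot sourceName short source identifier, e.g. \code{"EN"}.
#' @slot values numeric matrix, n samples x p features, finite entries only.
#' @export
setClass("SourceBlock",
  slots = c(sourceName = "character", values = "matrix"))

setValidity("SourceBlock", function(object) {
  v <- object@values
  if (length(object@sourceName) != 1L || !nzchar(object@sourceName))
    return("'sourceName' must be a single non-empty string")
  if (!is.numeric(v))
    return("'values' must be a numeric matrix")
  if (nrow(v) < 2L || ncol(v) < 1L)
    return("need at least 2 samples and 1 feature")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("'values' must carry sample IDs as rownames and feature names as colnames")
  if (anyDuplicated(rownames(v)))
    return("duplicate sample IDs")
  if (anyDuplicated(colnames(v)))
    return("duplicate feature names")
  if (!all(is.finite(v)))
    return("'values' contains missing or non-finite entries")
  TRUE
})

#' Construct a SourceBlock
#'
#' @param values numeric matrix with sample IDs as rownames and feature names
#'   as colnames. A data.frame is coerced.
#' @param sourceName short source identifier (e.g. \code{"ET"}).
#' @return A validated \linkS4class{SourceBlock}.
#' @examples
#' m <- matrix(rnorm(12), 4, 3,
#'   dimnames = list(paste0("S", 1:4), paste0("f", 1:3)))
#' SourceBlock(m, "EN")
#' @export
SourceBlock <- function(values, sourceName) {
  if (is.data.frame(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  methods::new("SourceBlock", sourceName = as.character(sourceName),
    values = values)
}

#' @describeIn SourceBlock source identifier
#' @param x a SourceBlock
#' @export
setMethod("sourceName", "SourceBlock", function(x) x@sourceName)

#' @describeIn SourceBlock sample IDs (row order)
#' @export
setMethod("sampleIds", "SourceBlock", function(x) rownames(x@values))

#' @describeIn SourceBlock feature names
#' @export
setMethod("featureNames", "SourceBlock", function(x) colnames(x@values))

#' @describeIn SourceBlock underlying matrix
#' @export
setMethod("featureValues", "SourceBlock", function(x) x@values)

setMethod("show", "SourceBlock", function(object) {
  cat(sprintf("SourceBlock '%s': %d samples x %d features\n",
    object@sourceName, nrow(object@values), ncol(object@values)))
})

#' MultiSourceDataset: aligned blocks plus class labels
#'
#' A collection of \linkS4class{SourceBlock} objects sharing one sample set in
#' one common order, with a per-sample class label. The class set order is the
#' factor level order of \code{labels}.
#'
#' @slot blocks named list of SourceBlock objects, identical sample order.
#' @slot labels factor of length n; levels are the ordered class set.
#' @export
setClass("MultiSourceDataset",
  slots = c(blocks = "list", labels = "factor"))

setValidity("MultiSourceDataset", function(object) {
  if (length(object@blocks) < 1L)
    return("need at least one block")
  if (!all(vapply(object@blocks, methods::is, logical(1), "SourceBlock")))
    return("all blocks must be SourceBlock objects")
  ids <- rownames(object@blocks[[1L]]@values)
  for (b in object@blocks)
    if (!identical(rownames(b@values), ids))
      return("all blocks must share identical sample IDs in identical order")
  nms <- unname(vapply(object@blocks, function(b) b@sourceName, character(1)))
  if (anyDuplicated(nms))
    return("duplicate source names")
  if (!identical(names(object@blocks), nms))
    return("list names must equal block source names")
  if (length(object@labels) != length(ids))
    return("labels length must equal sample count")
  if (anyNA(object@labels))
    return("labels contain NA")
  if (!all(levels(object@labels) %in% as.character(object@labels)))
    return("every class in the class set must have at least one sample")
  TRUE
})

#' Construct a MultiSourceDataset
#'
#' @param blocks list of \linkS4class{SourceBlock} objects with identical
#'   sample IDs (any order; they are re-ordered to the first block's order).
#' @param labels character or factor of per-sample class labels, named by
#'   sample ID or given in the first block's sample order. If character, the
#'   class set order is first appearance.
#' @return A validated \linkS4class{MultiSourceDataset}.
#' @export
MultiSourceDataset <- function(blocks, labels) {
  stopifnot(length(blocks) >= 1L)
  ref <- rownames(blocks[[1L]]@values)
  blocks <- lapply(blocks, function(b) {
    ids <- rownames(b@values)
    if (!setequal(ids, ref))
      stop("sample-ID sets differ between blocks", call. = FALSE)
    if (!identical(ids, ref))
      b@values <- b@values[ref, , drop = FALSE]
    b
  })
  names(blocks) <- vapply(blocks, function(b) b@sourceName, character(1))
  if (!is.null(names(labels))) {
    missing <- setdiff(ref, names(labels))
    if (length(missing))
      stop("samples present in blocks but absent from labels: ",
        paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
    labels <- labels[ref]
  } else if (length(labels) != length(ref)) {
    stop("labels length must equal sample count", call. = FALSE)
  }
  if (!is.factor(labels))
    labels <- factor(as.character(labels), levels = unique(as.character(labels)))
  labels <- droplevels(labels)
  names(labels) <- ref
  methods::new("MultiSourceDataset", blocks = blocks, labels = labels)
}

#' @describeIn MultiSourceDataset named list of blocks
#' @param x a MultiSourceDataset
#' @export
setMethod("blocks", "MultiSourceDataset", function(x) x@blocks)

#' @describeIn MultiSourceDataset shared sample IDs
#' @export
setMethod("sampleIds", "MultiSourceDataset",
  function(x) rownames(x@blocks[[1L]]@values))

#' @describeIn MultiSourceDataset per-sample class labels (factor)
#' @export
setMethod("classLabels", "MultiSourceDataset", function(x) x@labels)

#' Ordered class set of a dataset
#'
#' @param x a \linkS4class{MultiSourceDataset}.
#' @return Character vector of class names in class-set order.
#' @export
classNames <- function(x) levels(classLabels(x))

setMethod("show", "MultiSourceDataset", function(object) {
  n <- length(sampleIds(object))
  cat(sprintf("MultiSourceDataset: %d samples, %d sources, %d classes\n",
    n, length(object@blocks), nlevels(object@labels)))
  for (b in object@blocks)
    cat(sprintf("  %-6s %d features\n", b@sourceName, ncol(b@values)))
  tab <- table(object@labels)
  cat("  classes:",
    paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
})

#' StandardizationParams: fitted z-score statistics
#'
#' Column means and sample standard deviations (n-1 denominator) fitted on the
#' standardization rows, applied as \eqn{X'_{ij} = (X_{ij} - \bar X_j)/S_j}.
#'
#' @slot means per-column means.
#' @slot sds per-column sample standard deviations, all > 0.
#' @slot mode \code{"calibration"} (statistics from calibration rows only) or
#'   \code{"pooled"} (calibration and validation rows standardized jointly).
#' @export
setClass("StandardizationParams",
  slots = c(means = "numeric", sds = "numeric", mode = "character"))

setValidity("StandardizationParams", function(object) {
  if (length(object@means) != length(object@sds))
    return("means and sds must have equal length")
  if (!all(is.finite(object@sds)) || any(object@sds <= 0))
    return("all sds must be finite and > 0")
  if (!object@mode %in% c("calibration", "pooled"))
    return("mode must be 'calibration' or 'pooled'")
  TRUE
})

#' PCAModel: correlation-matrix PCA fitted on calibration rows
#'
#' Eigen-decomposition of the correlation matrix of the standardized
#' calibration block. Validation samples are scored by inserting their
#' standardized rows into the linear expression of each retained component
#' (\code{\link{projectScores}}); they never alter the model.
#'
#' @slot eigenvectors m x m matrix, unit-norm columns; in each column the
#'   largest-magnitude coefficient is positive.
#' @slot eigenvalues descending eigenvalues; sum equals m.
#' @slot varianceRatios eigenvalues / m.
#' @slot kSelected retained component count (cumulative variance rule).
#' @slot standardization the \linkS4class{StandardizationParams} used.
#' @slot calibScores n x kSelected fitted calibration score matrix.
#' @slot sourceName source identifier.
#' @export
setClass("PCAModel",
  slots = c(eigenvectors = "matrix", eigenvalues = "numeric",
    varianceRatios = "numeric", kSelected = "integer",
    standardization = "StandardizationParams", calibScores = "matrix",
    sourceName = "character"))

setValidity("PCAModel", function(object) {
  m <- ncol(object@eigenvectors)
  if (nrow(object@eigenvectors) != m)
    return("eigenvector matrix must be square (m x m)")
  if (length(object@eigenvalues) != m)
    return("need one eigenvalue per component")
  if (any(object@eigenvalues < -1e-10))
    return("eigenvalues must be non-negative (within 1e-10)")
  if (is.unsorted(rev(object@eigenvalues)))
    return("eigenvalues must be sorted descending")
  if (abs(sum(object@eigenvalues) - m) > 1e-8)
    return("eigenvalue sum must equal m (correlation-matrix PCA)")
  norms <- sqrt(colSums(object@eigenvectors^2))
  if (any(abs(norms - 1) > 1e-10))
    return("eigenvectors must have unit Euclidean norm")
  if (object@kSelected < 1L || object@kSelected > m)
    return("kSelected out of range")
  TRUE
})

#' @describeIn PCAModel source identifier
#' @param x a PCAModel
#' @export
setMethod("sourceName", "PCAModel", function(x) x@sourceName)

setMethod("show", "PCAModel", function(object) {
  cat(sprintf(
    "PCAModel (%s): %d variables, %d retained PCs (%.1f%% cumulative variance)\n",
    object@sourceName, ncol(object@eigenvectors), object@kSelected,
    100 * sum(object@varianceRatios[seq_len(object@kSelected)])))
})

#' PLSFeatureModel: NIPALS PLS components for feature extraction
#'
#' Sequentially extracted latent variables (deflated NIPALS) regressing a
#' centred one-hot class indicator on the standardized block. Calibration
#' scores come from the fit; new samples are scored by applying the stored
#' weights and loadings to their standardized rows.
#'
#' @slot xWeights p x A weight matrix W.
#' @slot xLoadings p x A loading matrix P.
#' @slot yLoadings K x A response-loading matrix Q.
#' @slot nLv retained latent-variable count A.
#' @slot calibScores n x A calibration T-score matrix.
#' @slot xMeans centring means of the predictor columns.
#' @slot yMeans centring means of the one-hot response.
#' @slot classes ordered class names encoded one-hot.
#' @slot standardization the \linkS4class{StandardizationParams} used.
#' @slot sourceName source identifier.
#' @export
setClass("PLSFeatureModel",
  slots = c(xWeights = "matrix", xLoadings = "matrix", yLoadings = "matrix",
    nLv = "integer", calibScores = "matrix", xMeans = "numeric",
    yMeans = "numeric",
    classes = "character", standardization = "StandardizationParams",
    sourceName = "character"))

setValidity("PLSFeatureModel", function(object) {
  A <- object@nLv
  if (A < 1L) return("nLv must be >= 1")
  if (ncol(object@xWeights) != A || ncol(object@xLoadings) != A ||
      ncol(object@yLoadings) != A || ncol(object@calibScores) != A)
    return("component counts inconsistent across slots")
  if (A > 1L) {
    TT <- crossprod(object@calibScores)
    if (max(abs(TT[upper.tri(TT)])) > 1e-8 * max(diag(TT)))
      return("calibration T-score columns must be pairwise orthogonal")
  }
  TRUE
})

#' @describeIn PLSFeatureModel source identifier
#' @param x a PLSFeatureModel
#' @export
setMethod("sourceName", "PLSFeatureModel", function(x) x@sourceName)

setMethod("show", "PLSFeatureModel", function(object) {
  cat(sprintf("PLSFeatureModel (%s): %d variables, %d latent variables\n",
    object@sourceName, nrow(object@xWeights), object@nLv))
})

#' FusedFeatures: mid-level fusion of per-source component scores
#'
#' Column-wise concatenation of per-source score matrices with provenance
#' feature names such as \code{"ET-PC1"} or \code{"EN-LV2"}, grouped
#' contiguously by source.
#'
#' @slot values n x q fused score matrix.
#' @slot sourceOrder source names in concatenation order.
#' @slot featureSource per-column source name (parallel to colnames).
#' @export
setClass("FusedFeatures",
  slots = c(values = "matrix", sourceOrder = "character",
    featureSource = "character"))

setValidity("FusedFeatures", function(object) {
  if (length(object@featureSource) != ncol(object@values))
    return("featureSource must have one entry per column")
  if (is.null(colnames(object@values)) || anyDuplicated(colnames(object@values)))
    return("fused feature names must be present and unique")
  r <- rle(object@featureSource)
  if (anyDuplicated(r$values) || !identical(r$values, object@sourceOrder))
    return("columns must be grouped contiguously by source in sourceOrder")
  TRUE
})

#' @describeIn FusedFeatures fused score matrix
#' @param x a FusedFeatures
#' @export
setMethod("featureValues", "FusedFeatures", function(x) x@values)

#' @describeIn FusedFeatures provenance feature names
#' @export
setMethod("featureNames", "FusedFeatures", function(x) colnames(x@values))

#' @describeIn FusedFeatures sample IDs
#' @export
setMethod("sampleIds", "FusedFeatures", function(x) rownames(x@values))

setMethod("show", "FusedFeatures", function(object) {
  cat(sprintf("FusedFeatures: %d samples x %d features from %s\n",
    nrow(object@values), ncol(object@values),
    paste(object@sourceOrder, collapse = " + ")))
})

#' Prediction: per-sample class assignments with continuous scores
#'
#' @slot labels per-sample assigned class or \code{"UNASSIGNED"}.
#' @slot scores n x K matrix of continuous per-class scores.
#' @slot classes ordered class names (score column order).
#' @slot tau assignment threshold applied to the maximal score.
#' @export
setClass("Prediction",
  slots = c(labels = "character", scores = "matrix", classes = "character",
    tau = "numeric"))

setValidity("Prediction", function(object) {
  if (length(object@labels) != nrow(object@scores))
    return("one label per score row required")
  if (!identical(colnames(object@scores), object@classes))
    return("score columns must be named by the class set")
  ok <- object@labels %in% c(object@classes, .UNASSIGNED)
  if (!all(ok)) return("labels must be classes or UNASSIGNED")
  TRUE
})

setMethod("show", "Prediction", function(object) {
  n <- length(object@labels)
  un <- sum(object@labels == .UNASSIGNED)
  cat(sprintf("Prediction: %d samples (%d unassigned), classes: %s, tau = %g\n",
    n, un, paste(object@classes, collapse = ", "), object@tau))
})

#' Predicted labels of a Prediction
#'
#' @param pred a \linkS4class{Prediction}.
#' @return Named character vector of assigned classes (\code{"UNASSIGNED"}
#'   where below threshold).
#' @export
predictedLabels <- function(pred) {
  stopifnot(methods::is(pred, "Prediction"))
  structure(pred@labels, names = rownames(pred@scores))
}

#' Continuous per-class scores of a Prediction
#'
#' @param pred a \linkS4class{Prediction}.
#' @return n x K numeric matrix of scores (columns in class order).
#' @export
predictionScores <- function(pred) {
  stopifnot(methods::is(pred, "Prediction"))
  pred@scores
}
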