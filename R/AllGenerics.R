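#' Source name of a block or model
#'
#' @param x a \linkS4class{SourceBlock}, \linkS4class{PCAModel} or other object
#'   carrying an instrument-source identifier.
#' @return A length-one character vector such as \code{"EN"} or \code{"HPLC"}.
#' @export
setGeneric("sourceName", function(x) standardGeneric("sourceName"))

#' Sample identifiers
#'
#' @param x an object holding per-sample rows.
#' @return Character vector of sample IDs in row order.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Feature names
#'
#' @param x an object holding named feature columns.
#' @return Character vector of feature (column) names.
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' Numeric feature matrix
#'
#' @param x an object wrapping a sample-by-feature matrix.
#' @return The underlying numeric matrix (samples in rows).
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' Per-source blocks of a multi-source dataset
#'
#' @param x a \linkS4class{MultiSourceDataset}.
#' @return Named list of \linkS4class{SourceBlock} objects.
#' @export
setGeneric("blocks", function(x) standardGeneric("blocks"))

#' Class labels of a dataset
#'
#' @param x a \linkS4class{MultiSourceDataset}.
#' @return Factor of per-sample class labels; levels are the ordered class set.
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' Classify samples with a trained model
#'
#' Applies a trained classifier to a feature matrix and returns a
#' \linkS4class{Prediction}. All back-ends share the assignment convention:
#' the per-sample class is the arg-max score class provided that score reaches
#' the model's assignment threshold \code{tau}, otherwise the sample is left
#' \code{"UNASSIGNED"}. Arg-max ties resolve to the earliest class in the
#' model's class order.
#'
#' @param model a trained \linkS4class{PLSDAClassifier},
#'   \linkS4class{SVMClassifier} or \linkS4class{BPNNClassifier}.
#' @param features numeric matrix (samples x features) on the same scale and
#'   with the same columns the model was trained on.
#' @return A \linkS4class{Prediction}.
#' @export
setGeneric("classify", function(model, features) standardGeneric("classify"))
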