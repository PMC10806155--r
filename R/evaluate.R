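#' @include AllClasses.R
NULL

#' EvaluationReport: confusion accounting with the unassigned convention
#'
#' Unassigned samples are excluded from the TP/FP/TN/FN counts but are counted
#' as errors in the overall accuracy. Two accuracy conventions are reported:
#' \code{acOverall} = (n - misclassified - unassigned)/n, the headline metric,
#' and \code{acPrinted} = TP/(TP + FP), the precision-like tabular convention.
#'
#' @slot counts named integer vector (TP, FP, TN, FN) over assigned samples,
#'   one-vs-rest with the designated positive class.
#' @slot se sensitivity TP/(TP + FN).
#' @slot sp specificity TN/(TN + FP).
#' @slot acOverall (n - misclassified - unassigned)/n.
#' @slot acPrinted TP/(TP + FP).
#' @slot misclassifiedIds IDs assigned to a wrong class.
#' @slot unassignedIds IDs below the assignment threshold.
#' @slot perClassAccuracy per true class, fraction assigned correctly.
#' @slot positiveClass the positive class used for Se/Sp.
#' @export
setClass("EvaluationReport",
  slots = c(counts = "integer", se = "numeric", sp = "numeric",
    acOverall = "numeric", acPrinted = "numeric",
    misclassifiedIds = "character", unassignedIds = "character",
    perClassAccuracy = "numeric", positiveClass = "character"))

setValidity("EvaluationReport", function(object) {
  if (!identical(names(object@counts), c("TP", "FP", "TN", "FN")))
    return("counts must be named TP, FP, TN, FN")
  if (any(object@counts < 0L)) return("counts must be non-negative")
  if (length(intersect(object@misclassifiedIds, object@unassignedIds)))
    return("misclassified and unassigned ID lists must be disjoint")
  rates <- c(object@se, object@sp, object@acOverall, object@acPrinted)
  if (any(!is.na(rates) & (rates < 0 | rates > 1)))
    return("all rates must lie in [0, 1]")
  TRUE
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf(
    "EvaluationReport (positive = %s): Ac = %.4f (%d misclassified, %d unassigned)\n",
    object@positiveClass, object@acOverall, length(object@misclassifiedIds),
    length(object@unassignedIds)))
  cat(sprintf("  Se = %.4f, Sp = %.4f, Ac[TP/(TP+FP)] = %.4f\n",
    object@se, object@sp, object@acPrinted))
})

#' Evaluate predictions against true labels
#'
#' Confusion accounting with the unassigned-sample convention: samples whose
#' best score fell below the threshold are excluded from the TP/FP/TN/FN
#' tallies but count as errors in the overall accuracy. Multi-class truth is
#' collapsed one-vs-rest for Se/Sp with \code{positiveClass} positive.
#'
#' @param truth per-sample true class labels (character or factor; names used
#'   as sample IDs when present).
#' @param predicted a \linkS4class{Prediction} or a character vector of
#'   assigned labels (possibly containing \code{"UNASSIGNED"}).
#' @param positiveClass the positive class for Se/Sp (must occur in truth).
#' @return An \linkS4class{EvaluationReport}.
#' @examples
#' truth <- rep(c("BS", "GE"), c(3, 3))
#' pred <- c("BS", "BS", "UNASSIGNED", "GE", "GE", "BS")
#' evaluatePredictions(truth, pred, positiveClass = "BS")
#' @export
evaluatePredictions <- function(truth, predicted, positiveClass) {
  labels <- if (methods::is(predicted, "Prediction"))
    predictedLabels(predicted) else as.character(predicted)
  truthChr <- as.character(truth)
  if (length(truthChr) != length(labels))
    stop("length mismatch between truth and predictions", call. = FALSE)
  if (!positiveClass %in% truthChr)
    stop("unknown positive class: ", positiveClass, call. = FALSE)
  ids <- names(truth)
  if (is.null(ids)) ids <- names(labels)
  if (is.null(ids)) ids <- paste0("S", seq_along(truthChr))
  n <- length(truthChr)
  unassigned <- labels == .UNASSIGNED
  mis <- !unassigned & labels != truthChr
  assigned <- !unassigned
  tpos <- truthChr == positiveClass
  ppos <- labels == positiveClass
  counts <- c(
    TP = sum(assigned & ppos & tpos),
    FP = sum(assigned & ppos & !tpos),
    TN = sum(assigned & !ppos & !tpos),
    FN = sum(assigned & !ppos & tpos))
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  perClass <- vapply(unique(truthChr), function(cl)
    sum(assigned & truthChr == cl & labels == cl) / sum(truthChr == cl),
    numeric(1))
  methods::new("EvaluationReport", counts = as.integer(counts) |>
      stats::setNames(names(counts)),
    se = div(counts[["TP"]], counts[["TP"]] + counts[["FN"]]),
    sp = div(counts[["TN"]], counts[["TN"]] + counts[["FP"]]),
    acOverall = (n - sum(mis) - sum(unassigned)) / n,
    acPrinted = div(counts[["TP"]], counts[["TP"]] + counts[["FP"]]),
    misclassifiedIds = ids[mis], unassignedIds = ids[unassigned],
    perClassAccuracy = perClass, positiveClass = positiveClass)
}

#' ROC curve and AUC from positive-class scores
#'
#' AUC is the Mann-Whitney pair statistic: the fraction of
#' (positive, negative) pairs whose scores are correctly ordered, with ties
#' counted one half. The stepwise ROC points (FPR, TPR at every distinct
#' threshold) are returned alongside.
#'
#' @param scores per-sample continuous score for the positive class.
#' @param truth per-sample labels; both classes must be present.
#' @param positiveClass label treated as positive (default: first of the
#'   sorted unique labels equal to \code{"BS"} if present, otherwise the
#'   first).
#' @return List with \code{auc} (numeric fraction) and \code{curve}
#'   (data.frame with columns threshold, fpr, tpr).
#' @examples
#' rocAuc(c(0.9, 0.8, 0.4, 0.3), c("BS", "O", "BS", "O"), "BS")$auc
#' @export
rocAuc <- function(scores, truth, positiveClass = NULL) {
  truth <- as.character(truth)
  if (is.null(positiveClass))
    positiveClass <- if ("BS" %in% truth) "BS" else sort(unique(truth))[1L]
  pos <- truth == positiveClass
  nP <- sum(pos); nN <- sum(!pos)
  if (nP == 0L || nN == 0L)
    stop("both classes must be present in truth", call. = FALSE)
  r <- rank(scores)   # mean ranks give the tie-corrected Mann-Whitney AUC
  auc <- (sum(r[pos]) - nP * (nP + 1) / 2) / (nP * nN)
  thr <- sort(unique(scores), decreasing = TRUE)
  curve <- data.frame(
    threshold = c(Inf, thr),
    fpr = c(0, vapply(thr, function(t) sum(!pos & scores >= t) / nN, 0)),
    tpr = c(0, vapply(thr, function(t) sum(pos & scores >= t) / nP, 0)))
  list(auc = auc, curve = curve)
}

#' Serialize an evaluation report to JSON
#'
#' @param report an \linkS4class{EvaluationReport}.
#' @param path optional output path; when omitted, the list is returned.
#' @return The report as a plain list (invisibly when written).
#' @export
exportReport <- function(report, path = NULL) {
  x <- list(positive_class = report@positiveClass,
    counts = as.list(report@counts), se = report@se, sp = report@sp,
    ac_overall = report@acOverall, ac_printed = report@acPrinted,
    misclassified_ids = report@misclassifiedIds,
    unassigned_ids = report@unassignedIds,
    per_class_accuracy = as.list(report@perClassAccuracy))
  if (!is.null(path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
      digits = NA)
    return(invisible(x))
  }
  x
}
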