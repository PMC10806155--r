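#' @include AllClasses.R
NULL

#' Mid-level fusion: concatenate per-source component scores
#'
#' Column-wise concatenation of per-source score matrices in the given order,
#' with provenance feature names \code{"<SOURCE>-PC<i>"} /
#' \code{"<SOURCE>-LV<i>"} taken from the score column names. No re-scaling is
#' applied at fusion time.
#'
#' @param scoreList named list of score matrices (names are the source names,
#'   e.g. \code{EN, EE, ET, HPLC}); all must share sample count and order.
#' @return A \linkS4class{FusedFeatures} of width \eqn{q = \sum_s k_s}.
#' @examples
#' a <- matrix(1:6, 3, 2, dimnames = list(NULL, c("PC1", "PC2")))
#' b <- matrix(1:3, 3, 1, dimnames = list(NULL, "PC1"))
#' featureNames(fuseBlocks(list(EN = a, ET = b)))
#' @export
fuseBlocks <- function(scoreList) {
  stopifnot(length(scoreList) >= 1L)
  srcs <- names(scoreList)
  if (is.null(srcs) || any(!nzchar(srcs)))
    stop("scoreList must be named by source", call. = FALSE)
  if (anyDuplicated(srcs))
    stop("duplicate source names: ",
      paste(unique(srcs[duplicated(srcs)]), collapse = ", "), call. = FALSE)
  ns <- vapply(scoreList, nrow, integer(1))
  if (length(unique(ns)) != 1L)
    stop("row-count mismatch between score blocks: ",
      paste(ns, collapse = ", "), call. = FALSE)
  ref <- rownames(scoreList[[1L]])
  for (m in scoreList)
    if (!is.null(ref) && !is.null(rownames(m)) &&
        !identical(rownames(m), ref))
      stop("sample order differs between score blocks", call. = FALSE)
  named <- mapply(function(m, s) {
    cn <- colnames(m)
    if (is.null(cn)) cn <- paste0("PC", seq_len(ncol(m)))
    colnames(m) <- paste0(s, "-", cn)
    m
  }, scoreList, srcs, SIMPLIFY = FALSE)
  fused <- do.call(cbind, named)
  methods::new("FusedFeatures", values = fused, sourceOrder = srcs,
    featureSource = rep(srcs, times = vapply(scoreList, ncol, integer(1))))
}

#' Write fused features to CSV
#'
#' @param fused a \linkS4class{FusedFeatures}.
#' @param path output CSV path.
#' @return Invisibly, \code{path}.
#' @export
writeFusedFeatures <- function(fused, path) {
  stopifnot(methods::is(fused, "FusedFeatures"))
  v <- featureValues(fused)
  df <- data.frame(sample_id = rownames(v), v, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
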