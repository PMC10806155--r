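#' @include AllClasses.R pca.R fuse.R
NULL

#' Univariate Wilk's lambda of one feature across groups
#'
#' The bounded one-way decomposition \eqn{\Lambda = SS_{within}/SS_{total}},
#' in [0, 1]: a smaller value means the group means explain more of the
#' feature's variation, i.e. stronger discriminant ability. Invariant to
#' affine rescaling of the feature.
#'
#' @param x numeric feature values, one per sample.
#' @param groups per-sample group labels (>= 2 groups, each non-empty).
#' @return Lambda in [0, 1].
#' @examples
#' wilksLambda(c(1, 2, 3, 4), c("a", "a", "b", "b"))  # 0.2
#' @export
wilksLambda <- function(x, groups) {
  groups <- as.factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  if (length(x) != length(groups))
    stop("x and groups must have equal length", call. = FALSE)
  sst <- sum((x - mean(x))^2)
  if (sst == 0)
    stop("Wilk's lambda undefined: zero total variance", call. = FALSE)
  ssw <- sum(vapply(levels(groups), function(g) {
    xi <- x[groups == g]
    sum((xi - mean(xi))^2)
  }, numeric(1)))
  ssw / sst
}

#' Factor loadings of a correlation-matrix PCA
#'
#' Default \code{mode = "correlation"}: \eqn{q_{ij} = \sqrt{\lambda_i}\,a_{ij}},
#' the Pearson correlation between component score i and standardized original
#' variable j, satisfying \eqn{\sum_j q_{ij}^2 = \lambda_i}. A literal mode
#' \eqn{q_{ij} = \lambda_i\, a_{ij}} is selectable.
#'
#' @param model a fitted \linkS4class{PCAModel}.
#' @param mode \code{"correlation"} (default) or \code{"literal"}.
#' @return m x m matrix q, rows components, columns original variables.
#' @export
factorLoadings <- function(model, mode = c("correlation", "literal")) {
  stopifnot(methods::is(model, "PCAModel"))
  mode <- match.arg(mode)
  fac <- if (mode == "correlation") sqrt(model@eigenvalues)
    else model@eigenvalues
  q <- fac * t(model@eigenvectors)
  dimnames(q) <- list(colnames(model@eigenvectors),
    rownames(model@eigenvectors))
  q
}

#' ContributionReport: per-feature discriminability and key variables
#'
#' @slot wilks data.frame (feature, source, lambda, rank) sorted ascending by
#'   lambda — smaller lambda, stronger contribution.
#' @slot topVariables data.frame (feature, variable, loading) naming, for each
#'   top-ranked PC-type fused feature, the original variable with maximal
#'   absolute factor loading.
#' @export
setClass("ContributionReport",
  slots = c(wilks = "data.frame", topVariables = "data.frame"))

setValidity("ContributionReport", function(object) {
  lam <- object@wilks$lambda
  if (any(lam < -1e-12 | lam > 1 + 1e-12))
    return("every lambda must lie in [0, 1]")
  if (is.unsorted(lam)) return("wilks table must be sorted ascending")
  TRUE
})

setMethod("show", "ContributionReport", function(object) {
  cat("ContributionReport: top discriminant fused features\n")
  print(utils::head(object@wilks, 5L), row.names = FALSE)
})

#' Rank fused features by discriminant contribution
#'
#' Computes the univariate Wilk's lambda of every fused feature on the
#' calibration samples and sorts ascending (smallest lambda = strongest
#' contribution). For the \code{topK} strongest PC-type features, the original
#' variable with the maximal absolute factor loading of that component is
#' reported, linking fused components back to instrument variables.
#'
#' @param fused \linkS4class{FusedFeatures} of the calibration samples only.
#' @param groups per-sample class labels (calibration).
#' @param models named list of per-source \linkS4class{PCAModel}s (optional;
#'   needed to resolve top variables for PC features).
#' @param topK how many top features to resolve to original variables
#'   (default 4; 0 gives an empty top list).
#' @return A \linkS4class{ContributionReport}.
#' @export
rankContributions <- function(fused, groups, models = list(), topK = 4L) {
  stopifnot(methods::is(fused, "FusedFeatures"))
  v <- featureValues(fused)
  if (nrow(v) != length(groups))
    stop("group/sample mismatch", call. = FALSE)
  lam <- apply(v, 2L, wilksLambda, groups = groups)
  ord <- order(lam)
  wilks <- data.frame(feature = colnames(v)[ord],
    source = fused@featureSource[ord], lambda = unname(lam[ord]),
    rank = seq_along(ord), stringsAsFactors = FALSE)
  top <- wilks[0, c("feature", "source")]
  top$variable <- character(0); top$loading <- numeric(0)
  if (topK > 0L) {
    cand <- utils::head(wilks, topK)
    rows <- lapply(seq_len(nrow(cand)), function(i) {
      feat <- cand$feature[i]
      comp <- sub("^.*-", "", feat)
      if (!grepl("^PC[0-9]+$", comp)) return(NULL)
      src <- cand$source[i]
      if (is.null(models[[src]])) return(NULL)
      q <- factorLoadings(models[[src]])
      j <- which.max(abs(q[comp, ]))
      data.frame(feature = feat, source = src,
        variable = colnames(q)[j], loading = unname(q[comp, j]),
        stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) top <- do.call(rbind, rows)
  }
  methods::new("ContributionReport", wilks = wilks, topVariables = top)
}

#' Export a contribution report as CSV
#'
#' Writes the ranked Wilk's-lambda table (feature, source, lambda, rank) and,
#' when present, a top-variable table alongside
#' (\code{<path>} and \code{<path base>_top_variables.csv}).
#'
#' @param report a \linkS4class{ContributionReport}.
#' @param path output CSV path for the lambda table.
#' @return Invisibly, \code{path}.
#' @export
exportContributions <- function(report, path) {
  utils::write.csv(report@wilks, path, row.names = FALSE, quote = FALSE)
  if (nrow(report@topVariables)) {
    utils::write.csv(report@topVariables,
      sub("\\.csv$", "_top_variables.csv", path), row.names = FALSE,
      quote = FALSE)
  }
  invisible(path)
}

#' Weighted fingerprint similarity (weighted cosine)
#'
#' Similarity between a sample's chromatographic peak-area vector and a
#' control fingerprint, with per-peak weights: marker peaks (e.g. militarine)
#' can be up-weighted relative to common peaks.
#' \deqn{sim = \frac{\sum_j w_j x_j r_j}{\sqrt{\sum_j w_j x_j^2 \cdot \sum_j w_j r_j^2}}}
#' With equal weights this reduces to ordinary cosine similarity; for
#' non-negative peak areas the value lies in [0, 1].
#'
#' @param x sample peak-area vector.
#' @param control control fingerprint (e.g. from [controlFingerprint()]).
#' @param weights positive per-peak weights (default all 1).
#' @return Similarity value.
#' @examples
#' fingerprintSimilarity(c(1, 0), c(1, 1), weights = c(2.5, 1))
#' @export
fingerprintSimilarity <- function(x, control, weights = NULL) {
  if (length(x) != length(control))
    stop("sample and control must have equal length", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(x))
  if (length(weights) != length(x) || any(weights <= 0))
    stop("weights must be positive and match the peak count", call. = FALSE)
  nx <- sum(weights * x^2); nr <- sum(weights * control^2)
  if (nx == 0 || nr == 0)
    stop("zero-norm vector in similarity computation", call. = FALSE)
  sum(weights * x * control) / sqrt(nx * nr)
}

#' Mean control fingerprint of a reference class
#'
#' @param peaks n x p matrix of peak areas (samples in rows).
#' @param referenceIds row IDs of the reference-class samples.
#' @return The column-mean peak vector over the reference samples.
#' @export
controlFingerprint <- function(peaks, referenceIds) {
  stopifnot(all(referenceIds %in% rownames(peaks)))
  colMeans(peaks[referenceIds, , drop = FALSE])
}

#' Per-peak weight vector with up-weighted marker peaks
#'
#' Convenience for the common-peak weighting scheme in which marker
#' metabolites (e.g. militarine) receive weight 2.5 and all other peaks 1.
#'
#' @param nPeaks number of peaks.
#' @param marker index (or indices) of the marker peak(s).
#' @param markerWeight weight of the marker peak(s), default 2.5.
#' @return Numeric weight vector.
#' @export
peakWeights <- function(nPeaks, marker, markerWeight = 2.5) {
  w <- rep(1, nPeaks)
  w[marker] <- markerWeight
  w
}
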