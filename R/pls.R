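#' @include AllClasses.R
NULL

# one-hot encoding of a factor, columns in level order
.oneHot <- function(labels) {
  labels <- as.factor(labels)
  Y <- matrix(0, length(labels), nlevels(labels),
    dimnames = list(names(labels), levels(labels)))
  Y[cbind(seq_along(labels), as.integer(labels))] <- 1
  Y
}

.matrixRank <- function(x) qr(x)$rank

#' NIPALS partial least squares for feature extraction
#'
#' Sequential NIPALS extraction with deflation of both the predictor and the
#' response matrix. X and the one-hot response are centred by their
#' calibration means before extraction; the calibration T-scores are pairwise
#' orthogonal. New samples are scored by applying the stored weights and
#' loadings to their (identically standardized) rows — see [plsScores()] and
#' [plsResponse()].
#'
#' @param calStd standardized calibration matrix (n x p, with dimnames).
#' @param labels per-sample class labels (factor or character); encoded
#'   one-hot in level order.
#' @param nLv number of latent variables to extract (>= 1, <= rank of
#'   \code{calStd}).
#' @param sourceName source identifier stored in the model.
#' @param standardization optional \linkS4class{StandardizationParams} carried
#'   for auditing.
#' @return A \linkS4class{PLSFeatureModel}.
#' @export
fitPLS <- function(calStd, labels, nLv, sourceName = "X",
    standardization = NULL) {
  stopifnot(is.matrix(calStd))
  nLv <- as.integer(nLv)
  if (nLv < 1L) stop("nLv must be >= 1", call. = FALSE)
  rk <- .matrixRank(scale(calStd, center = TRUE, scale = FALSE))
  if (nLv > rk)
    stop("nLv (", nLv, ") exceeds the rank of the calibration matrix (",
      rk, ")", call. = FALSE)
  labels <- as.factor(labels)
  Y <- .oneHot(labels)
  yMeans <- colMeans(Y)
  xMeans <- colMeans(calStd)
  E <- sweep(calStd, 2L, xMeans)
  F <- sweep(Y, 2L, yMeans)
  p <- ncol(E); K <- ncol(F); n <- nrow(E)
  W <- matrix(0, p, nLv, dimnames = list(colnames(calStd), paste0("LV", 1:nLv)))
  P <- W
  Q <- matrix(0, K, nLv, dimnames = list(colnames(Y), paste0("LV", 1:nLv)))
  TT <- matrix(0, n, nLv, dimnames = list(rownames(calStd), paste0("LV", 1:nLv)))
  for (a in seq_len(nLv)) {
    u <- F[, which.max(apply(F, 2L, stats::var))]
    tOld <- rep(Inf, n)
    for (iter in seq_len(500L)) {
      w <- crossprod(E, u)
      w <- w / sqrt(sum(w^2))
      tvec <- E %*% w
      q <- crossprod(F, tvec) / c(crossprod(tvec))
      u <- F %*% q / c(crossprod(q))
      if (sqrt(sum((tvec - tOld)^2)) < 1e-12 * sqrt(sum(tvec^2))) break
      tOld <- tvec
    }
    pvec <- crossprod(E, tvec) / c(crossprod(tvec))
    W[, a] <- w; P[, a] <- pvec; Q[, a] <- q; TT[, a] <- tvec
    E <- E - tvec %*% t(pvec)
    F <- F - tvec %*% t(q)
  }
  if (is.null(standardization))
    standardization <- methods::new("StandardizationParams",
      means = stats::setNames(rep(0, p), colnames(calStd)),
      sds = stats::setNames(rep(1, p), colnames(calStd)),
      mode = "calibration")
  methods::new("PLSFeatureModel", xWeights = W, xLoadings = P,
    yLoadings = Q, nLv = nLv, calibScores = TT,
    xMeans = stats::setNames(xMeans, colnames(calStd)), yMeans = yMeans,
    classes = levels(labels), standardization = standardization,
    sourceName = sourceName)
}

# latent-variable scores of new (standardized) rows: sequential deflation
.plsNewScores <- function(model, rows) {
  if (is.null(dim(rows))) rows <- matrix(rows, nrow = 1L)
  if (ncol(rows) != nrow(model@xWeights))
    stop("column-count mismatch with PLS model", call. = FALSE)
  En <- sweep(rows, 2L, model@xMeans)
  A <- model@nLv
  TT <- matrix(0, nrow(rows), A,
    dimnames = list(rownames(rows), colnames(model@xWeights)))
  for (a in seq_len(A)) {
    tvec <- En %*% model@xWeights[, a]
    TT[, a] <- tvec
    En <- En - tvec %*% t(model@xLoadings[, a])
  }
  TT
}

#' Latent-variable scores for new samples
#'
#' @param model a \linkS4class{PLSFeatureModel}.
#' @param rows matrix of samples standardized identically to the calibration
#'   matrix the model was fitted on.
#' @return n x nLv score matrix with columns \code{LV1..LVA}.
#' @export
plsScores <- function(model, rows) {
  stopifnot(methods::is(model, "PLSFeatureModel"))
  .plsNewScores(model, rows)
}

#' Predicted class-indicator values from a PLS model
#'
#' @param model a \linkS4class{PLSFeatureModel}.
#' @param rows standardized sample matrix.
#' @param nLv number of components to use (default: all retained).
#' @return n x K matrix of predicted one-hot indicator values.
#' @export
plsResponse <- function(model, rows, nLv = model@nLv) {
  TT <- .plsNewScores(model, rows)[, seq_len(nLv), drop = FALSE]
  Yhat <- TT %*% t(model@yLoadings[, seq_len(nLv), drop = FALSE])
  sweep(Yhat, 2L, model@yMeans, "+")
}

#' Select the latent-variable count by leave-one-out cross-validation
#'
#' For each left-out sample, a PLS model with \code{maxLv} components is
#' fitted on the remaining rows and the sample is classified (arg-max
#' predicted indicator) with every component count 1..maxLv. Returns the
#' count minimizing the leave-one-out misclassification rate; ties resolve to
#' the smallest count. A \code{maxLv} exceeding the matrix rank is clipped
#' with a warning.
#'
#' @param calStd standardized calibration matrix.
#' @param labels per-sample class labels.
#' @param maxLv largest candidate component count (default 15).
#' @return The selected component count (integer). The per-count LOOCV error
#'   counts are attached as \code{attr(, "errors")}.
#' @export
selectNlvLOOCV <- function(calStd, labels, maxLv = 15L) {
  labels <- as.factor(labels)
  n <- nrow(calStd)
  rk <- .matrixRank(scale(calStd, center = TRUE, scale = FALSE))
  maxLv <- as.integer(maxLv)
  if (maxLv < 1L) stop("maxLv must be >= 1", call. = FALSE)
  if (maxLv > rk) {
    maxLv <- rk
    warning("maxLv clipped to ", maxLv, " (rank of calibration matrix)",
      call. = FALSE)
  }
  errors <- integer(maxLv)
  for (i in seq_len(n)) {
    Xi <- calStd[-i, , drop = FALSE]
    # leaving one row out can reduce the rank below maxLv
    kFold <- min(maxLv, .matrixRank(scale(Xi, center = TRUE, scale = FALSE)))
    fit <- fitPLS(Xi, labels[-i], kFold)
    resp <- vapply(seq_len(maxLv), function(k) {
      r <- plsResponse(fit, calStd[i, , drop = FALSE], nLv = min(k, kFold))
      colnames(r)[which.max(r)]
    }, character(1))
    errors <- errors + (resp != as.character(labels[i]))
  }
  k <- which.min(errors)   # which.min takes the first (smallest) minimiser
  structure(as.integer(k), errors = errors)
}
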