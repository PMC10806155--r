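#' @include AllClasses.R
NULL

#' Correlation-matrix PCA on a standardized calibration block
#'
#' Eigen-decomposes the correlation matrix of the standardized calibration
#' matrix (equivalently, \eqn{X'X/(n-1)} of the z-scored matrix). Eigenvalues
#' are sorted descending; each eigenvector is oriented so its
#' largest-magnitude coefficient is positive, giving a reproducible sign
#' convention. The retained component count is the smallest k whose cumulative
#' variance ratio reaches \code{varianceThreshold}.
#'
#' Validation samples never enter the fit; score them afterwards with
#' [projectScores()].
#'
#' @param calStd standardized calibration matrix (columns must have sample
#'   standard deviation 1; checked to 1e-6, otherwise a contract error).
#' @param varianceThreshold cumulative explained-variance fraction for
#'   component retention (default 0.90, i.e. "at least 90\%").
#' @param standardization optional \linkS4class{StandardizationParams} to
#'   carry with the model (for auditing which statistics produced
#'   \code{calStd}).
#' @param sourceName source identifier stored in the model.
#' @return A \linkS4class{PCAModel}.
#' @examples
#' x <- matrix(rnorm(40), 10, 4,
#'   dimnames = list(paste0("S", 1:10), paste0("f", 1:4)))
#' z <- standardizeBlock(x, rownames(x))
#' fitPCA(z$values)
#' @export
fitPCA <- function(calStd, varianceThreshold = 0.90,
    standardization = NULL, sourceName = "X") {
  stopifnot(is.matrix(calStd), nrow(calStd) >= 2L)
  n <- nrow(calStd)
  sdv <- apply(calStd, 2L, stats::sd)
  if (any(abs(sdv - 1) > 1e-6))
    stop("input is not standardized: column sd deviates from 1 (",
      paste(utils::head(colnames(calStd)[abs(sdv - 1) > 1e-6], 3L),
        collapse = ", "), ")", call. = FALSE)
  m <- ncol(calStd)
  R <- crossprod(scale(calStd, center = TRUE, scale = FALSE)) / (n - 1)
  eig <- eigen(R, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  V <- eig$vectors
  for (i in seq_len(m)) {
    top <- which.max(abs(V[, i]))
    if (V[top, i] < 0) V[, i] <- -V[, i]
  }
  dimnames(V) <- list(colnames(calStd), paste0("PC", seq_len(m)))
  ratios <- lambda / sum(lambda)
  k <- which(cumsum(ratios) >= varianceThreshold - 1e-12)[1L]
  if (is.na(k)) k <- m
  scores <- calStd %*% V[, seq_len(k), drop = FALSE]
  if (is.null(standardization))
    standardization <- methods::new("StandardizationParams",
      means = stats::setNames(rep(0, m), colnames(calStd)),
      sds = stats::setNames(rep(1, m), colnames(calStd)),
      mode = "calibration")
  methods::new("PCAModel", eigenvectors = V, eigenvalues = lambda,
    varianceRatios = ratios, kSelected = as.integer(k),
    standardization = standardization, calibScores = scores,
    sourceName = sourceName)
}

#' Project standardized rows onto the retained principal components
#'
#' Computes \eqn{Z_i = \sum_j a_{ij} X'_j} for each retained component: new
#' samples are inserted into the linear expression of each PC fitted on the
#' calibration set, so scoring validation rows never alters the model.
#' Projecting the calibration matrix itself reproduces the fitted calibration
#' scores.
#'
#' @param model a \linkS4class{PCAModel}.
#' @param rows matrix of samples standardized with the model's own
#'   \linkS4class{StandardizationParams}; column count must equal m.
#' @return n x kSelected score matrix with columns \code{PC1..PCk}.
#' @export
projectScores <- function(model, rows) {
  stopifnot(methods::is(model, "PCAModel"))
  if (is.null(dim(rows))) rows <- matrix(rows, nrow = 1L)
  if (ncol(rows) != nrow(model@eigenvectors))
    stop("column-count mismatch: model has ", nrow(model@eigenvectors),
      " variables, rows have ", ncol(rows), call. = FALSE)
  rows %*% model@eigenvectors[, seq_len(model@kSelected), drop = FALSE]
}
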