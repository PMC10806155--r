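#' @include AllClasses.R AllGenerics.R pls.R
NULL

# shared assignment rule: arg-max score if it reaches tau, else UNASSIGNED;
# arg-max ties -> earliest class in class order (which.max), logged
.assign <- function(scores, classes, tau) {
  labs <- character(nrow(scores))
  for (i in seq_len(nrow(scores))) {
    s <- scores[i, ]
    j <- which.max(s)
    if (sum(s == s[j]) > 1L)
      message("arg-max tie for row ", i, "; assigned earliest class in order")
    labs[i] <- if (s[j] >= tau) classes[j] else .UNASSIGNED
  }
  labs
}

.newPrediction <- function(scores, classes, tau) {
  colnames(scores) <- classes
  methods::new("Prediction", labels = .assign(scores, classes, tau),
    scores = scores, classes = classes, tau = tau)
}

## ------------------------------------------------------------------ PLS-DA

#' PLSDAClassifier: PLS-DA with an unassigned-sample convention
#'
#' @slot pls the underlying \linkS4class{PLSFeatureModel} (one-hot response).
#' @slot classes ordered class names.
#' @slot tau assignment threshold on the predicted indicator value, in (0,1).
#' @export
setClass("PLSDAClassifier",
  slots = c(pls = "PLSFeatureModel", classes = "character", tau = "numeric"))

setValidity("PLSDAClassifier", function(object) {
  if (object@tau <= 0 || object@tau >= 1)
    return("tau must lie strictly between 0 and 1")
  TRUE
})

setMethod("show", "PLSDAClassifier", function(object) {
  cat(sprintf("PLSDAClassifier: %d classes, %d latent variables, tau = %g\n",
    length(object@classes), object@pls@nLv, object@tau))
})

#' Train a PLS-DA classifier
#'
#' Regresses the centred one-hot class indicator on the features via NIPALS
#' PLS ([fitPLS()]). Prediction assigns each sample to the arg-max predicted
#' indicator class provided that value reaches \code{tau}; otherwise the
#' sample is reported \code{"UNASSIGNED"}.
#'
#' @param features numeric feature matrix (standardized block, component
#'   scores or fused scores).
#' @param labels per-sample class labels (>= 2 classes).
#' @param nLv number of latent variables (choose with [selectNlvLOOCV()]).
#' @param tau assignment threshold on the predicted indicator, default 0.5.
#' @return A \linkS4class{PLSDAClassifier}.
#' @export
trainPLSDA <- function(features, labels, nLv, tau = 0.5) {
  labels <- as.factor(labels)
  if (nlevels(labels) < 2L)
    stop("need at least 2 classes", call. = FALSE)
  pls <- fitPLS(features, labels, nLv)
  methods::new("PLSDAClassifier", pls = pls, classes = levels(labels),
    tau = tau)
}

#' @rdname classify
#' @export
setMethod("classify", "PLSDAClassifier", function(model, features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  scores <- plsResponse(model@pls, features)
  .newPrediction(scores, model@classes, model@tau)
})

## --------------------------------------------------------------------- SVM

#' SVMClassifier: binary RBF-kernel SVM selected by grid search
#'
#' The dual quadratic program is solved by libsvm (via e1071); the kernel
#' parameterization is \eqn{K(x,y) = \exp(-g\,\|x-y\|^2)}. Grid generation,
#' stratified fold construction, the cross-validated error loop and the
#' winner-selection logic live in this package (see [trainSVMGrid()]).
#'
#' @slot g kernel parameter (gamma), > 0.
#' @slot cost penalty parameter c, > 0.
#' @slot fit the fitted libsvm model (refit on all training rows).
#' @slot classes the two class names, training level order.
#' @slot nSupportVectors support-vector count of the final fit.
#' @slot cvErrors grid of cross-validated error rates (g x cost).
#' @slot foldIds the seed-fixed fold assignment used for selection.
#' @slot tau assignment threshold on the class score (default 0: the signed
#'   decision value always assigns one of the two classes).
#' @export
setClass("SVMClassifier",
  slots = c(g = "numeric", cost = "numeric", fit = "ANY",
    classes = "character", nSupportVectors = "integer", cvErrors = "matrix",
    foldIds = "integer", tau = "numeric"))

setMethod("show", "SVMClassifier", function(object) {
  cat(sprintf(
    "SVMClassifier (RBF): g = %.4g, cost = %.4g, %d support vectors, CV error %.4f\n",
    object@g, object@cost, object@nSupportVectors,
    object@cvErrors[paste0("g=", signif(object@g, 6)),
      paste0("c=", signif(object@cost, 6))]))
})

#' Default kernel-parameter grid (geometric, ratio sqrt(2))
#'
#' \eqn{g = 0.05\cdot(\sqrt 2)^k, k = 0..15}: after rounding to two decimals
#' this produces 0.05, 0.07, 0.1, 0.14, 0.2, 0.28, 0.4, 0.57, 0.8, 1.13, 1.6,
#' 2.26, 3.2, 4.53, 6.4, 9.05 — the conventional \eqn{\sqrt 2}-spaced search
#' set for RBF kernels.
#'
#' @return Numeric vector of 16 kernel parameters.
#' @export
defaultGammaGrid <- function() 0.05 * sqrt(2)^(0:15)

#' Default cost grid
#'
#' @return \code{c(0.1, 1, 10)}.
#' @export
defaultCostGrid <- function() c(0.1, 1, 10)

#' Seed-fixed stratified fold assignment
#'
#' Shuffles each class's samples with the given seed and deals them to folds
#' round-robin, so every fold's class proportions match the data as closely as
#' possible and the assignment is reproducible.
#'
#' @param labels per-sample class labels.
#' @param k fold count; every class must have at least k members.
#' @param seed integer seed for the within-class shuffles.
#' @return Integer vector of fold IDs in 1..k.
#' @export
makeStratifiedFolds <- function(labels, k = 10L, seed = 1L) {
  labels <- as.factor(labels)
  k <- as.integer(k)
  if (any(table(labels) < k))
    stop("fold count too large: a class would be absent from some fold",
      call. = FALSE)
  set.seed(seed)
  folds <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' RBF kernel matrix
#'
#' \eqn{K(x,y) = \exp(-g\,\|x-y\|^2)}. Symmetric with unit diagonal for
#' \code{Y = X}, and positive semi-definite for every g > 0.
#'
#' @param X n x p matrix.
#' @param Y m x p matrix (default X).
#' @param g kernel parameter, > 0.
#' @return n x m kernel matrix.
#' @export
rbfKernel <- function(X, Y = X, g) {
  stopifnot(g > 0)
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  exp(-g * pmax(d2, 0))
}

.svmFit <- function(features, labels, g, cost) {
  e1071::svm(x = features, y = labels, scale = FALSE, type = "C-classification",
    kernel = "radial", gamma = g, cost = cost)
}

#' Cross-validated error of one RBF-SVM parameter pair
#'
#' @param features training feature matrix.
#' @param labels binary factor labels.
#' @param g,cost RBF kernel and penalty parameters.
#' @param foldIds fold assignment from [makeStratifiedFolds()].
#' @return Misclassification rate across held-out folds.
#' @export
svmCvError <- function(features, labels, g, cost, foldIds) {
  labels <- as.factor(labels)
  wrong <- 0L
  for (f in sort(unique(foldIds))) {
    test <- foldIds == f
    fit <- .svmFit(features[!test, , drop = FALSE], droplevels(labels[!test]),
      g, cost)
    pred <- stats::predict(fit, features[test, , drop = FALSE])
    wrong <- wrong + sum(as.character(pred) != as.character(labels[test]))
  }
  wrong / length(labels)
}

#' Train a binary RBF-SVM by stratified-CV grid search
#'
#' Evaluates every (g, cost) pair by stratified k-fold cross-validation with a
#' fold assignment fixed by \code{seed}, selects the pair with minimal CV
#' error — ties resolve to the fewest support vectors of the full refit, then
#' to the larger cost, then to the smaller g — and refits the winner on all
#' training rows.
#'
#' @param features training feature matrix.
#' @param labels exactly two classes.
#' @param gGrid kernel-parameter candidates (default [defaultGammaGrid()]).
#' @param cGrid cost candidates (default [defaultCostGrid()]).
#' @param folds fold count for cross-validation (default 10).
#' @param seed seed fixing the fold assignment.
#' @return An \linkS4class{SVMClassifier}.
#' @export
trainSVMGrid <- function(features, labels, gGrid = defaultGammaGrid(),
    cGrid = defaultCostGrid(), folds = 10L, seed = 1L) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L)
    stop("the SVM back-end is binary only (use PLS-DA or BP-NN for ",
      "multi-class tasks)", call. = FALSE)
  if (!length(gGrid) || !length(cGrid))
    stop("empty parameter grid", call. = FALSE)
  foldIds <- makeStratifiedFolds(labels, folds, seed)
  cv <- matrix(NA_real_, length(gGrid), length(cGrid),
    dimnames = list(paste0("g=", signif(gGrid, 6)),
      paste0("c=", signif(cGrid, 6))))
  for (i in seq_along(gGrid))
    for (j in seq_along(cGrid))
      cv[i, j] <- svmCvError(features, labels, gGrid[i], cGrid[j], foldIds)
  cand <- which(cv == min(cv), arr.ind = TRUE)
  if (nrow(cand) > 1L) {
    nsv <- apply(cand, 1L, function(idx)
      .svmFit(features, labels, gGrid[idx[1L]], cGrid[idx[2L]])$tot.nSV)
    cand <- cand[nsv == min(nsv), , drop = FALSE]
    if (nrow(cand) > 1L) {
      cand <- cand[cGrid[cand[, 2L]] == max(cGrid[cand[, 2L]]), , drop = FALSE]
      cand <- cand[which.min(gGrid[cand[, 1L]]), , drop = FALSE]
    }
  }
  g <- gGrid[cand[1L, 1L]]; cost <- cGrid[cand[1L, 2L]]
  fit <- .svmFit(features, labels, g, cost)
  methods::new("SVMClassifier", g = g, cost = cost, fit = fit,
    classes = levels(labels), nSupportVectors = as.integer(fit$tot.nSV),
    cvErrors = cv, foldIds = foldIds, tau = 0)
}

#' @rdname classify
#' @export
setMethod("classify", "SVMClassifier", function(model, features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  pred <- stats::predict(model@fit, features, decision.values = TRUE)
  d <- attr(pred, "decision.values")
  pair <- strsplit(colnames(d)[1L], "/", fixed = TRUE)[[1L]]
  scores <- matrix(0, nrow(features), 2L,
    dimnames = list(rownames(features), model@classes))
  scores[, pair[1L]] <- d[, 1L]
  scores[, pair[2L]] <- -d[, 1L]
  .newPrediction(scores, model@classes, model@tau)
})

## ------------------------------------------------------------------- BP-NN

#' BPNNClassifier: momentum back-propagation network
#'
#' Fully connected network with logistic-sigmoid activations throughout,
#' squared-error loss and full-batch gradient descent with a momentum term:
#' \eqn{\Delta w(t) = -\eta \nabla E + \alpha \Delta w(t-1)}.
#'
#' @slot weights list of layer weight matrices, each (nIn + 1) x nOut with the
#'   bias in the first row.
#' @slot hidden hidden-layer sizes.
#' @slot learningRate step size eta, > 0.
#' @slot momentum momentum coefficient alpha in [0, 1).
#' @slot iterations training iteration count, >= 0.
#' @slot seed weight-initialization seed.
#' @slot classes ordered class names (output units).
#' @slot tau assignment threshold on the output activation.
#' @slot errorTrace squared-error loss before each update plus after the last
#'   (length iterations + 1).
#' @export
setClass("BPNNClassifier",
  slots = c(weights = "list", hidden = "integer", learningRate = "numeric",
    momentum = "numeric", iterations = "integer", seed = "integer",
    classes = "character", tau = "numeric", errorTrace = "numeric"))

setValidity("BPNNClassifier", function(object) {
  if (object@learningRate <= 0) return("learningRate must be > 0")
  if (object@momentum < 0 || object@momentum >= 1)
    return("momentum must be in [0, 1)")
  if (object@iterations < 0L) return("iterations must be >= 0")
  if (length(object@hidden) && any(object@hidden < 1L))
    return("zero-size hidden layer")
  TRUE
})

setMethod("show", "BPNNClassifier", function(object) {
  cat(sprintf(
    "BPNNClassifier: layers %s, eta = %g, momentum = %g, %d iterations\n",
    paste(c(nrow(object@weights[[1L]]) - 1L, object@hidden,
      length(object@classes)), collapse = "-"),
    object@learningRate, object@momentum, object@iterations))
})

.sigmoid <- function(z) 1 / (1 + exp(-z))

# forward pass; returns list of activations per layer (input first)
.bpnnForward <- function(weights, X) {
  act <- vector("list", length(weights) + 1L)
  act[[1L]] <- X
  for (l in seq_along(weights))
    act[[l + 1L]] <- .sigmoid(cbind(1, act[[l]]) %*% weights[[l]])
  act
}

.bpnnInitWeights <- function(sizes, seed) {
  set.seed(seed)
  lapply(seq_len(length(sizes) - 1L), function(l)
    matrix(stats::runif((sizes[l] + 1L) * sizes[l + 1L], -0.5, 0.5),
      sizes[l] + 1L, sizes[l + 1L]))
}

#' Train a momentum back-propagation network
#'
#' Full-batch squared-error gradient descent,
#' \eqn{E = \tfrac12\sum_n\sum_k (y_{nk} - o_{nk})^2}, with the update
#' \eqn{\Delta w(t) = -\eta\nabla E + \alpha\Delta w(t-1)}. Weights are
#' initialized uniformly in (-0.5, 0.5) from \code{seed};
#' \code{iterations = 0} returns the seeded initialization untouched.
#' Training aborts with a divergence error naming the iteration if the loss
#' becomes non-finite.
#'
#' @param features training feature matrix (standardized or component
#'   scores).
#' @param labels per-sample class labels (one output unit per class).
#' @param hidden integer vector of hidden-layer sizes (may be empty for a
#'   single-layer network); e.g. \code{c(10, 10)} for two hidden layers of 10.
#' @param learningRate step size eta (default 0.01).
#' @param momentum momentum term alpha in [0,1) (default 0.5).
#' @param iterations full-batch iterations (default 500).
#' @param seed weight-initialization seed.
#' @param tau assignment threshold on output activations (default 0.5).
#' @return A trained \linkS4class{BPNNClassifier}.
#' @export
trainBPNN <- function(features, labels, hidden = c(10L, 10L),
    learningRate = 0.01, momentum = 0.5, iterations = 500L, seed = 1L,
    tau = 0.5) {
  labels <- as.factor(labels)
  X <- as.matrix(features)
  Y <- .oneHot(labels)
  sizes <- c(ncol(X), as.integer(hidden), ncol(Y))
  if (any(sizes < 1L)) stop("zero-size layer", call. = FALSE)
  weights <- .bpnnInitWeights(sizes, seed)
  velocity <- lapply(weights, function(w) w * 0)
  iterations <- as.integer(iterations)
  trace <- numeric(iterations + 1L)
  L <- length(weights)
  for (it in seq_len(iterations)) {
    act <- .bpnnForward(weights, X)
    out <- act[[L + 1L]]
    E <- 0.5 * sum((Y - out)^2)
    if (!is.finite(E))
      stop("divergence (non-finite loss) at iteration ", it,
        "; reduce the learning rate", call. = FALSE)
    trace[it] <- E
    delta <- (out - Y) * out * (1 - out)
    for (l in rev(seq_len(L))) {
      grad <- crossprod(cbind(1, act[[l]]), delta)
      if (l > 1L) {
        a <- act[[l]]
        delta <- (delta %*% t(weights[[l]][-1L, , drop = FALSE])) * a * (1 - a)
      }
      velocity[[l]] <- -learningRate * grad + momentum * velocity[[l]]
      weights[[l]] <- weights[[l]] + velocity[[l]]
    }
  }
  out <- .bpnnForward(weights, X)[[L + 1L]]
  trace[iterations + 1L] <- 0.5 * sum((Y - out)^2)
  methods::new("BPNNClassifier", weights = weights,
    hidden = as.integer(hidden), learningRate = learningRate,
    momentum = momentum, iterations = iterations, seed = as.integer(seed),
    classes = levels(labels), tau = tau, errorTrace = trace)
}

#' @rdname classify
#' @export
setMethod("classify", "BPNNClassifier", function(model, features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  act <- .bpnnForward(model@weights, as.matrix(features))
  scores <- act[[length(act)]]
  rownames(scores) <- rownames(features)
  .newPrediction(scores, model@classes, model@tau)
})
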