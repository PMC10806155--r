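## ----------------------------------------------------------------- PLS-DA

test_that("PLS-DA separates two clean clusters and respects the threshold", {
  cd <- clusterData(n = 15, sep = 8, seed = 1)
  model <- trainPLSDA(cd$X, cd$labels, nLv = 2)
  pred <- classify(model, cd$X)
  # nearest-template assignment on the same draw as the independent check
  mu <- apply(cd$X, 2, function(col) tapply(col, cd$labels, mean))
  nearest <- levels(cd$labels)[apply(cd$X, 1, function(r)
    which.min(colSums((t(mu) - r)^2)))]
  expect_identical(unname(predictedLabels(pred)), nearest)
  expect_identical(unname(predictedLabels(pred)), as.character(cd$labels))
  expect_error(trainPLSDA(cd$X, factor(rep("A", 30)), nLv = 1),
    "at least 2 classes")
  expect_error(trainPLSDA(cd$X, cd$labels, nLv = 10), "rank")
})

test_that("every training sample is assigned in a low-noise 4-class run", {
  ds <- generateDataset(scenarioConfig(
    classSizes = c(BS = 10L, GE = 10L, PO = 10L, BOS = 10L),
    sourceDims = c(EN = 8L), noiseSd = 0.05, seed = 2))
  v <- featureValues(blocks(ds)$EN)
  z <- standardizeBlock(v, rownames(v))$values
  model <- trainPLSDA(z, classLabels(ds), nLv = 3, tau = 0.5)
  pred <- classify(model, z)
  expect_false(any(predictedLabels(pred) == unassignedLabel()))
  expect_identical(unname(predictedLabels(pred)),
    as.character(classLabels(ds)))
})

test_that("the assignment convention follows the threshold rule", {
  scores <- rbind(c(0.2, 0.3), c(0.9, 0.1), c(0.5, 0.5))
  classes <- c("BS", "OTHER")
  mk <- function(tau) senseFuse:::.newPrediction(scores, classes, tau)
  p <- suppressMessages(mk(0.5))
  expect_identical(p@labels[1], unassignedLabel())  # (0.2, 0.3) below tau
  expect_identical(p@labels[2], "BS")               # (0.9, 0.1) assigned
  expect_identical(p@labels[3], "BS")               # tie -> earliest class
  p0 <- suppressMessages(mk(0))
  expect_identical(p0@labels, c("OTHER", "BS", "BS"))  # tau 0: plain arg-max
})

## -------------------------------------------------------------------- SVM

test_that("the sqrt(2) kernel grid reproduces the conventional values", {
  g <- round(defaultGammaGrid(), 2)
  expect_true(all(c(0.05, 0.4, 0.57, 0.8, 1.13, 1.6, 2.26, 3.2, 4.53, 6.4,
    9.05) %in% g))
  expect_length(defaultGammaGrid(), 16L)
})

test_that("RBF kernel matrices are symmetric PSD with unit diagonal", {
  set.seed(3)
  X <- matrix(rnorm(40), 10, 4)
  for (g in c(0.05, 1.13, 9.05)) {
    K <- rbfKernel(X, g = g)
    expect_equal(unname(diag(K)), rep(1, 10), tolerance = 1e-12)
    expect_equal(K, t(K), tolerance = 1e-12)
    expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
      -1e-8)
  }
})

test_that("grid search matches an independent CV recomputation on ring data", {
  rd <- ringData(n = 25, seed = 4)
  g <- defaultGammaGrid()[c(4, 8, 12, 16)]
  cc <- c(0.1, 1, 10)
  model <- trainSVMGrid(rd$X, rd$y, gGrid = g, cGrid = cc, folds = 5,
    seed = 11)
  folds <- makeStratifiedFolds(rd$y, 5, seed = 11)
  ref <- svmGridOracle(rd$X, rd$y, g, cc, folds)
  expect_equal(min(model@cvErrors), min(ref), tolerance = 1e-12)
  expect_equal(unname(model@cvErrors), ref, tolerance = 1e-12)
  # the ring is not linearly separable, yet some RBF grid point fits it
  train <- classify(model, rd$X)
  expect_lte(sum(predictedLabels(train) != as.character(rd$y)), 1L)
  # single-pair grid is selected trivially
  m1 <- trainSVMGrid(rd$X, rd$y, gGrid = 1.13, cGrid = 10, folds = 5)
  expect_equal(m1@g, 1.13)
  expect_equal(m1@cost, 10)
})

test_that("smaller cost recruits more support vectors on the ring", {
  rd <- ringData(n = 25, seed = 5)
  lo <- trainSVMGrid(rd$X, rd$y, gGrid = 1, cGrid = 0.1, folds = 5)
  hi <- trainSVMGrid(rd$X, rd$y, gGrid = 1, cGrid = 10, folds = 5)
  expect_gt(lo@nSupportVectors, hi@nSupportVectors)
})

test_that("the SVM back-end refuses multi-class labels", {
  z <- stdMatrix(12, 3, seed = 6)
  expect_error(trainSVMGrid(z, factor(rep(c("A", "B", "C"), 4))),
    "binary only")
})

## ------------------------------------------------------------------ BP-NN

test_that("zero iterations return the seeded initialization exactly", {
  cd <- clusterData(n = 5, seed = 7)
  model <- trainBPNN(cd$X, cd$labels, hidden = 4L, iterations = 0, seed = 42)
  sizes <- c(3L, 4L, 2L)
  set.seed(42)   # independent reconstruction of the initial weights
  expected <- lapply(1:2, function(l)
    matrix(runif((sizes[l] + 1L) * sizes[l + 1L], -0.5, 0.5),
      sizes[l] + 1L, sizes[l + 1L]))
  expect_identical(model@weights, expected)
})

test_that("the second update equals -eta*grad + alpha * first update", {
  X <- matrix(2, 1, 1, dimnames = list("S1", "f"))
  lab <- factor("A")
  eta <- 0.3; alpha <- 0.6
  w <- lapply(0:2, function(it) trainBPNN(X, lab, hidden = integer(0),
    learningRate = eta, momentum = alpha, iterations = it, seed = 5,
    tau = 0.5)@weights[[1]])
  grad <- function(W) {    # hand gradient of E = 0.5 (y - sigmoid(b + w x))^2
    z <- W[1] + W[2] * 2
    o <- 1 / (1 + exp(-z))
    d <- (o - 1) * o * (1 - o)
    c(d, d * 2)
  }
  d1 <- w[[2]] - w[[1]]
  d2 <- w[[3]] - w[[2]]
  expect_equal(as.vector(d1), -eta * grad(w[[1]]), tolerance = 1e-12)
  expect_equal(as.vector(d2), -eta * grad(w[[2]]) + alpha * as.vector(d1),
    tolerance = 1e-12)
})

test_that("500 momentum iterations drive separable data to zero error", {
  cd <- clusterData(n = 20, sep = 8, seed = 8)
  model <- trainBPNN(cd$X, cd$labels, hidden = c(10L, 10L),
    learningRate = 0.01, momentum = 0.5, iterations = 500, seed = 1)
  pred <- classify(model, cd$X)
  expect_identical(sum(predictedLabels(pred) != as.character(cd$labels)), 0L)
  tr <- model@errorTrace
  expect_true(all(is.finite(tr)))
  expect_lt(tr[length(tr)], tr[1])
})

test_that("training keeps the loss finite even under an absurd step size", {
  cd <- clusterData(n = 10, seed = 9)
  model <- trainBPNN(cd$X, cd$labels, hidden = 3L, learningRate = 1e4,
    iterations = 200, seed = 1)
  expect_true(all(is.finite(model@errorTrace)))
  expect_error(trainBPNN(cd$X, cd$labels, hidden = 0L), "layer")
})

test_that("classification is deterministic for a fixed model", {
  cd <- clusterData(n = 10, seed = 10)
  model <- trainBPNN(cd$X, cd$labels, hidden = 5L, iterations = 50, seed = 2)
  expect_identical(classify(model, cd$X), classify(model, cd$X))
})
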