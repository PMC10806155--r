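test_that("first latent variable of a one-column block is the column itself", {
  set.seed(1)
  x <- matrix(rnorm(10), 10, 1, dimnames = list(paste0("S", 1:10), "f"))
  lab <- factor(rep(c("A", "B"), 5))
  fit <- fitPLS(x, lab, nLv = 1)
  centred <- x - mean(x)
  ratio <- fit@calibScores[, 1] / centred[, 1]
  expect_equal(max(ratio) - min(ratio), 0, tolerance = 1e-10)
})

test_that("NIPALS weights and scores match an independent reference loop", {
  for (seed in c(2, 3, 4)) {
    set.seed(seed)
    X <- matrix(rnorm(18), 6, 3,
      dimnames = list(paste0("S", 1:6), paste0("f", 1:3)))
    lab <- factor(c("A", "A", "B", "B", "C", "C"))
    Y <- outer(lab, levels(lab), "==") * 1
    fit <- fitPLS(X, lab, nLv = 2)
    ref <- nipalsOracle(X, Y, 2)
    for (a in 1:2) {
      s <- sign(sum(fit@xWeights[, a] * ref$W[, a]))
      expect_equal(unname(fit@xWeights[, a]), s * ref$W[, a],
        tolerance = 1e-8)
      expect_equal(unname(fit@calibScores[, a]), s * ref$T[, a],
        tolerance = 1e-8)
      expect_equal(unname(fit@xLoadings[, a]), s * ref$P[, a],
        tolerance = 1e-8)
    }
  }
})

test_that("calibration T-scores are pairwise orthogonal", {
  z <- stdMatrix(n = 20, p = 5, seed = 5)
  lab <- factor(rep(c("A", "B"), 10))
  fit <- fitPLS(z, lab, nLv = 4)
  G <- crossprod(fit@calibScores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8 * max(diag(G)))
})

test_that("full-rank PLS predictions coincide with ordinary least squares", {
  set.seed(6)
  X <- matrix(rnorm(24), 8, 3,
    dimnames = list(paste0("S", 1:8), paste0("f", 1:3)))
  lab <- factor(rep(c("A", "B"), 4))
  fit <- fitPLS(X, lab, nLv = 3)
  pls <- plsResponse(fit, X)
  Y <- outer(lab, levels(lab), "==") * 1
  ols <- cbind(1, X) %*% qr.coef(qr(cbind(1, X)), Y)
  expect_equal(unname(pls), unname(ols), tolerance = 1e-6)
})

test_that("scoring new samples never alters the fitted model", {
  z <- stdMatrix(n = 15, p = 4, seed = 7)
  lab <- factor(rep(c("A", "B", "C"), 5))
  fit <- fitPLS(z, lab, nLv = 2)
  before <- fit@xWeights
  invisible(plsScores(fit, matrix(rnorm(8), 2, 4)))
  expect_identical(fit@xWeights, before)
  # self-consistency of the sequential scorer
  expect_equal(plsScores(fit, z), fit@calibScores, tolerance = 1e-8)
})

test_that("requesting more components than the rank fails", {
  x <- matrix(rnorm(10), 10, 1, dimnames = list(paste0("S", 1:10), "f"))
  expect_error(fitPLS(x, factor(rep(c("A", "B"), 5)), nLv = 2), "rank")
})

test_that("LOOCV picks the component count the signal requires", {
  expect_identical(
    as.integer(selectNlvLOOCV(stdMatrix(10, 2, seed = 8),
      factor(rep(c("A", "B"), 5)), maxLv = 1)), 1L)
  # class signal recoverable only after removing a dominant nuisance
  # direction: the first latent variable cannot separate, the second can
  set.seed(9)
  n <- 40
  nuisance <- rnorm(n)
  cls <- rep(c(-1, 1), each = n / 2)
  X <- cbind(cls + 4 * nuisance, nuisance + rnorm(n, sd = 0.1))
  dimnames(X) <- list(paste0("S", 1:n), c("f1", "f2"))
  z <- standardizeBlock(X, rownames(X))$values
  lab <- factor(rep(c("A", "B"), each = n / 2))
  k <- selectNlvLOOCV(z, lab, maxLv = 2)
  expect_identical(as.integer(k), 2L)
  errs <- attr(k, "errors")
  expect_lt(errs[2], errs[1])
  # exhaustive LOOCV evaluation coded independently on the oracle NIPALS
  Y <- outer(lab, levels(lab), "==") * 1
  oracleErrs <- vapply(1:2, function(kk) {
    wrong <- 0L
    for (i in seq_len(n)) {
      ref <- nipalsOracle(z[-i, ], Y[-i, ], kk)
      En <- z[i, , drop = FALSE] -
        matrix(colMeans(z[-i, ]), 1)
      tv <- numeric(kk)
      for (a in seq_len(kk)) {
        tv[a] <- En %*% ref$W[, a]
        En <- En - tv[a] * t(ref$P[, a, drop = FALSE])
      }
      yhat <- tv %*% t(ref$Q) + colMeans(Y[-i, ])
      if (levels(lab)[which.max(yhat)] != as.character(lab[i]))
        wrong <- wrong + 1L
    }
    wrong
  }, integer(1))
  expect_identical(unname(errs), unname(oracleErrs))
  # separable clusters: the returned count achieves zero LOOCV error
  cd <- clusterData(n = 10, seed = 10)
  k2 <- selectNlvLOOCV(cd$X, cd$labels, maxLv = 2)
  expect_identical(attr(k2, "errors")[as.integer(k2)], 0L)
  expect_warning(selectNlvLOOCV(cd$X, cd$labels, maxLv = 50), "clipped")
})
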