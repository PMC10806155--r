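test_that("rank-1 correlation structure yields a single retained component", {
  x <- matrix(rnorm(10), 10, 1)
  m <- cbind(x, 2 * x + 3)          # perfectly correlated pair
  dimnames(m) <- list(paste0("S", 1:10), c("a", "b"))
  z <- standardizeBlock(m, rownames(m))$values
  fit <- fitPCA(z)
  expect_equal(fit@eigenvalues, c(2, 0), tolerance = 1e-10)
  expect_equal(fit@varianceRatios, c(1, 0), tolerance = 1e-10)
  expect_identical(fit@kSelected, 1L)
})

test_that("component retention follows the cumulative variance rule", {
  # ratios (0.60, 0.25, 0.10, 0.05) with threshold 0.90 -> k = 3
  lam <- c(0.60, 0.25, 0.10, 0.05) * 4
  expect_identical(which(cumsum(lam / sum(lam)) >= 0.90)[1], 3L)
  z <- stdMatrix(n = 30, p = 4, seed = 2)
  fit <- fitPCA(z, varianceThreshold = 0.90)
  k <- fit@kSelected
  ratios <- cumsum(fit@varianceRatios)
  expect_gte(ratios[k], 0.90)
  if (k > 1) expect_lt(ratios[k - 1], 0.90)
  expect_equal(sum(fit@varianceRatios), 1, tolerance = 1e-10)
})

test_that("eigen-decomposition matches a direct solve of cor(X)", {
  z <- stdMatrix(n = 5, p = 3, seed = 3)
  fit <- fitPCA(z)
  ref <- eigen(cor(z), symmetric = TRUE)   # independent dense eigen-solve
  expect_equal(fit@eigenvalues, ref$values, tolerance = 1e-8)
  for (i in 1:3)
    expect_equal(unname(abs(fit@eigenvectors[, i])), abs(ref$vectors[, i]),
      tolerance = 1e-8)
  # sign convention: largest-magnitude coefficient positive
  for (i in 1:3)
    expect_gt(fit@eigenvectors[which.max(abs(fit@eigenvectors[, i])), i], 0)
})

test_that("non-standardized input violates the fit contract", {
  set.seed(4)
  raw <- matrix(rnorm(30, sd = 3), 10, 3,
    dimnames = list(paste0("S", 1:10), paste0("f", 1:3)))
  expect_error(fitPCA(raw), "not standardized")
})

test_that("score projection is self-consistent, linear and leakage-free", {
  set.seed(5)
  m <- matrix(rnorm(60), 15, 4,
    dimnames = list(paste0("S", 1:15), paste0("f", 1:4)))
  cal <- paste0("S", 1:10)
  std <- standardizeBlock(m, cal)
  fit <- fitPCA(std$values[cal, ], sourceName = "EN")
  # projecting the calibration matrix reproduces the fitted scores
  expect_equal(projectScores(fit, std$values[cal, ]), fit@calibScores,
    tolerance = 1e-8)
  # a row at the calibration means scores exactly zero
  expect_equal(unname(projectScores(fit, rep(0, 4))[1, ]),
    rep(0, fit@kSelected), tolerance = 1e-12)
  # hand dot-product: 2-variable model, a1 = (0.7071, 0.7071), row (1,1)
  x2 <- matrix(rnorm(10), 10, 1)
  m2 <- cbind(x2, x2 * 1.0001)
  dimnames(m2) <- list(paste0("S", 1:10), c("a", "b"))
  z2 <- standardizeBlock(m2, rownames(m2))$values
  f2 <- fitPCA(z2)
  expect_equal(unname(f2@eigenvectors[, 1]), c(0.7071, 0.7071),
    tolerance = 1e-4)
  expect_equal(unname(projectScores(f2, c(1, 1))[1, 1]), 1.4142,
    tolerance = 1e-4)
  expect_error(projectScores(fit, matrix(0, 1, 3)), "mismatch")
})

test_that("perturbing validation rows never alters model or scores", {
  set.seed(6)
  m <- matrix(rnorm(80), 20, 4,
    dimnames = list(paste0("S", 1:20), paste0("f", 1:4)))
  cal <- paste0("S", 1:14)
  val <- paste0("S", 15:20)
  fitOnce <- function(mm) {
    std <- standardizeBlock(mm, cal, mode = "calibration")
    fitPCA(std$values[cal, ])
  }
  a <- fitOnce(m)
  m2 <- m
  m2[val, ] <- matrix(runif(24, -1e5, 1e5), 6, 4)
  b <- fitOnce(m2)
  expect_identical(a@eigenvectors, b@eigenvectors)
  expect_identical(a@eigenvalues, b@eigenvalues)
  expect_identical(a@calibScores, b@calibScores)
})
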