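test_that("Wilk's lambda hits its analytic boundary cases", {
  expect_equal(wilksLambda(c(1, 2, 1, 2), c("a", "a", "b", "b")), 1)
  expect_equal(wilksLambda(c(1, 1, 5, 5), c("a", "a", "b", "b")), 0)
  expect_equal(wilksLambda(c(1, 2, 3, 4), c("a", "a", "b", "b")), 0.2)
  expect_error(wilksLambda(rep(2, 4), c("a", "a", "b", "b")), "zero total")
  expect_error(wilksLambda(1:4, rep("a", 4)), "2 groups")
})

test_that("lambda equals brute-force sums of squares and is scale invariant", {
  for (seed in 1:20) {
    set.seed(seed)
    x <- rnorm(30)
    g <- sample(letters[1:4], 30, replace = TRUE)
    if (length(unique(g)) < 2) next
    lam <- wilksLambda(x, g)
    expect_equal(lam, wilksOracle(x, g), tolerance = 1e-10)
    expect_gte(lam, 0); expect_lte(lam, 1)
    expect_equal(wilksLambda(-3.7 * x + 11, g), lam, tolerance = 1e-10)
  }
})

test_that("factor loadings satisfy the eigen identities on random models", {
  for (seed in 1:50) {
    z <- stdMatrix(n = 20, p = 4, seed = seed)
    fit <- fitPCA(z)
    q <- factorLoadings(fit)
    expect_equal(unname(rowSums(q^2)), fit@eigenvalues, tolerance = 1e-8)
    expect_lte(max(abs(q)), 1 + 1e-8)
    # q_ij is the empirical score-variable Pearson correlation
    allScores <- z %*% fit@eigenvectors
    keep <- fit@eigenvalues > 1e-8
    expect_equal(unname(q[keep, , drop = FALSE]),
      unname(t(cor(z, allScores[, keep, drop = FALSE]))), tolerance = 1e-8)
  }
})

test_that("unit eigenvalue and literal mode behave as the formulas dictate", {
  set.seed(3)
  x1 <- rnorm(200); x2 <- rnorm(200)
  m <- cbind(x1, x2)
  dimnames(m) <- list(paste0("S", 1:200), c("a", "b"))
  z <- standardizeBlock(m, rownames(m))$values
  fit <- fitPCA(z)
  q <- factorLoadings(fit)
  expect_equal(unname(q), unname(sqrt(fit@eigenvalues) * t(fit@eigenvectors)),
    tolerance = 1e-12)
  lit <- factorLoadings(fit, mode = "literal")
  expect_equal(unname(lit), unname(fit@eigenvalues * t(fit@eigenvectors)),
    tolerance = 1e-12)
})

test_that("a known 2x2 correlation structure yields the closed-form loadings", {
  set.seed(4)
  n <- 2000
  x <- rnorm(n)
  y <- 0.6 * x + sqrt(1 - 0.36) * rnorm(n)   # population correlation 0.6
  m <- cbind(x, y)
  dimnames(m) <- list(paste0("S", 1:n), c("a", "b"))
  z <- standardizeBlock(m, rownames(m))$values
  r <- cor(z)[1, 2]
  fit <- fitPCA(z)
  expect_equal(fit@eigenvalues, c(1 + r, 1 - r), tolerance = 1e-10)
  expect_equal(abs(unname(fit@eigenvectors[, 1])), rep(0.7071, 2),
    tolerance = 1e-4)
  q <- factorLoadings(fit)
  expect_equal(q[1, 1], sqrt(1 + r) * fit@eigenvectors[1, 1],
    tolerance = 1e-12)
  expect_equal(sum(q[1, ]^2), 1 + r, tolerance = 1e-10)
})

test_that("contribution ranking surfaces the class-informative fused feature", {
  set.seed(5)
  n <- 60
  g <- rep(c("A", "B", "C"), each = 20)
  informative <- as.integer(factor(g)) + rnorm(n, sd = 0.05)
  noise <- matrix(rnorm(3 * n), n, 3)
  scores <- cbind(informative, noise)
  colnames(scores) <- paste0("PC", 1:4)
  rownames(scores) <- paste0("S", 1:n)
  fused <- fuseBlocks(list(ET = scores))
  cr <- rankContributions(fused, g, topK = 0L)
  expect_identical(cr@wilks$feature[1], "ET-PC1")
  expect_lt(cr@wilks$lambda[1], 0.1)
  expect_identical(nrow(cr@topVariables), 0L)
  expect_identical(cr@wilks$rank, 1:4)
})

test_that("pure-noise features never masquerade as discriminant", {
  mins <- vapply(1:20, function(seed) {
    set.seed(seed)
    scores <- matrix(rnorm(400), 100, 4,
      dimnames = list(paste0("S", 1:100), paste0("PC", 1:4)))
    g <- rep(c("A", "B", "C", "D"), each = 25)
    fused <- fuseBlocks(list(EN = scores))
    min(rankContributions(fused, g, topK = 0L)@wilks$lambda)
  }, numeric(1))
  expect_gt(min(mins), 0.5)
})

test_that("top variables resolve PC features through the loading matrix", {
  ds <- generateDataset(scenarioConfig(seed = 6))
  sp <- splitDataset(ds, 100)
  cal <- sp@calibrationIds
  models <- list(); scores <- list()
  for (b in blocks(ds)) {
    std <- standardizeBlock(b, cal)
    fit <- fitPCA(std$values[cal, , drop = FALSE], sourceName = sourceName(b))
    models[[sourceName(b)]] <- fit
    scores[[sourceName(b)]] <- projectScores(fit, std$values[cal, ])
  }
  fused <- fuseBlocks(scores)
  cr <- rankContributions(fused, classLabels(ds)[cal], models, topK = 4L)
  expect_identical(nrow(cr@topVariables), 4L)
  for (i in seq_len(4)) {
    src <- cr@topVariables$source[i]
    comp <- sub("^.*-", "", cr@topVariables$feature[i])
    q <- factorLoadings(models[[src]])
    expect_identical(cr@topVariables$variable[i],
      names(which.max(abs(q[comp, ]))))
  }
})

test_that("weighted cosine similarity follows the stated formula", {
  expect_equal(fingerprintSimilarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(fingerprintSimilarity(c(1, 0), c(0, 1)), 0)
  expect_equal(fingerprintSimilarity(c(1, 0), c(1, 1), weights = c(2.5, 1)),
    2.5 / sqrt(2.5 * 3.5), tolerance = 1e-12)
  set.seed(7)
  x <- runif(8); ctr <- runif(8)
  expect_equal(fingerprintSimilarity(x, ctr, weights = rep(4, 8)),
    sum(x * ctr) / sqrt(sum(x^2) * sum(ctr^2)), tolerance = 1e-12)
  expect_error(fingerprintSimilarity(c(0, 0), c(1, 1)), "zero-norm")
  expect_error(fingerprintSimilarity(1:3, 1:2), "equal length")
  w <- peakWeights(14, marker = 14)
  expect_equal(w[14], 2.5)
  expect_equal(sum(w), 13 + 2.5)
})

test_that("the control fingerprint is the reference-class mean", {
  m <- matrix(1:12 + 0.0, 4, 3, dimnames = list(paste0("S", 1:4), NULL))
  expect_equal(unname(controlFingerprint(m, c("S1", "S2"))),
    unname(colMeans(m[1:2, ])))
})
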