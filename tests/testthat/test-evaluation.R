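test_that("perfect prediction scores 1 on every rate", {
  truth <- rep(c("BS", "GE", "PO"), each = 4)
  rep1 <- evaluatePredictions(truth, truth, positiveClass = "BS")
  expect_equal(rep1@acOverall, 1)
  expect_equal(rep1@se, 1)
  expect_equal(rep1@sp, 1)
  expect_length(rep1@misclassifiedIds, 0L)
  expect_length(rep1@unassignedIds, 0L)
})

test_that("unassigned samples count as errors but stay out of the confusion", {
  truth <- rep(c("BS", "OTHER"), c(40, 60))
  pred <- truth
  pred[1] <- "OTHER"                 # one misclassified
  pred[50] <- unassignedLabel()      # one unassigned
  r <- evaluatePredictions(truth, pred, "BS")
  expect_equal(r@acOverall, 0.98)
  expect_equal(sum(r@counts), 99L)   # TP+FP+TN+FN excludes the unassigned
  expect_identical(r@misclassifiedIds, "S1")
  expect_identical(r@unassignedIds, "S50")
})

test_that("the printed Se/Sp/Ac formulas are honoured exactly", {
  # TP=33, FN=2, TN=64, FP=1
  truth <- rep(c("BS", "O"), c(35, 65))
  pred <- c(rep("BS", 33), rep("O", 2), "BS", rep("O", 64))
  r <- evaluatePredictions(truth, pred, "BS")
  expect_identical(r@counts, setNames(c(33L, 1L, 64L, 2L),
    c("TP", "FP", "TN", "FN")))
  expect_equal(r@se, 33 / 35)
  expect_equal(r@sp, 64 / 65)
  expect_equal(r@acPrinted, 33 / 34)
  expect_equal(r@acOverall, 97 / 100)
})

test_that("rates are invariant to sample permutation", {
  set.seed(1)
  truth <- sample(rep(c("BS", "GE", "PO"), each = 10))
  pred <- truth
  pred[c(3, 17)] <- c("GE", unassignedLabel())
  r1 <- evaluatePredictions(truth, pred, "BS")
  perm <- sample(30)
  r2 <- evaluatePredictions(truth[perm], pred[perm], "BS")
  expect_equal(r1@se, r2@se)
  expect_equal(r1@sp, r2@sp)
  expect_equal(r1@acOverall, r2@acOverall)
})

test_that("errors on malformed evaluation inputs", {
  expect_error(evaluatePredictions(c("a", "b"), "a", "a"), "length")
  expect_error(evaluatePredictions(c("a", "b"), c("a", "b"), "zz"),
    "unknown positive class")
})

test_that("AUC equals the exhaustive pair-counting statistic", {
  r <- rocAuc(c(0.9, 0.8, 0.4, 0.3), c("p", "n", "p", "n"), "p")
  expect_equal(r$auc, 0.75)
  expect_equal(r$auc, aucOracle(c(0.9, 0.8, 0.4, 0.3), c(TRUE, FALSE, TRUE,
    FALSE)))
  for (seed in 1:10) {
    set.seed(seed)
    s <- rnorm(30)
    pos <- runif(30) > 0.5
    if (!any(pos) || all(pos)) next
    truth <- ifelse(pos, "p", "n")
    expect_equal(rocAuc(s, truth, "p")$auc, aucOracle(s, pos),
      tolerance = 1e-12)
    # complement identity for tie-free scores
    expect_equal(rocAuc(s, truth, "p")$auc + rocAuc(-s, truth, "p")$auc, 1,
      tolerance = 1e-12)
  }
})

test_that("degenerate score patterns hit the AUC boundary values", {
  expect_equal(rocAuc(c(3, 4, 1, 2), c("p", "p", "n", "n"), "p")$auc, 1)
  expect_equal(rocAuc(rep(1, 6), rep(c("p", "n"), 3), "p")$auc, 0.5)
  expect_error(rocAuc(1:3, rep("p", 3), "p"), "both classes")
  curve <- rocAuc(c(0.9, 0.8, 0.4, 0.3), c("p", "n", "p", "n"), "p")$curve
  expect_equal(curve$fpr[1], 0)
  expect_equal(curve$tpr[nrow(curve)], 1)
  expect_true(all(diff(curve$fpr) >= 0) && all(diff(curve$tpr) >= 0))
})

test_that("AUC agrees with an established ROC implementation", {
  set.seed(2)
  s <- rnorm(40)
  truth <- rep(c("p", "n"), 20)
  ours <- rocAuc(s, truth, "p")$auc
  ref <- as.numeric(pROC::auc(pROC::roc(response = truth, predictor = s,
    levels = c("n", "p"), direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})
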