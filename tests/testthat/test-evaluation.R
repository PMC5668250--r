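countsToVectors <- function(tp, fp, tn, fn) {
  truth <- rep(c("binding", "non-binding"), c(tp + fn, tn + fp))
  calls <- c(rep("binding", tp), rep("non-binding", fn),
             rep("non-binding", tn), rep("binding", fp))
  list(truth = truth, calls = calls)
}

test_that("metrics reproduce hand-computed confusion examples", {
  # perfect predictor
  d <- countsToVectors(5, 0, 5, 0)
  m <- metricValues(classificationMetrics(d$truth, d$calls))
  expect_equal(unname(m[c("Sn", "Sp", "Acc", "MCC")]), c(1, 1, 1, 1))
  # chance
  d <- countsToVectors(5, 5, 5, 5)
  m <- metricValues(classificationMetrics(d$truth, d$calls))
  expect_equal(unname(m[c("Acc", "MCC")]), c(0.5, 0))
  # worked example: TP=8, FN=2, TN=7, FP=3
  d <- countsToVectors(8, 3, 7, 2)
  rep <- classificationMetrics(d$truth, d$calls)
  m <- metricValues(rep)
  expect_equal(unname(m[["Sn"]]), 0.8)
  expect_equal(unname(m[["Sp"]]), 0.7)
  expect_equal(unname(m[["Acc"]]), 0.75)
  expect_equal(unname(m[["MCC"]]),
               (8 * 7 - 3 * 2) / sqrt(11 * 10 * 10 * 9))
  expect_equal(round(unname(m[["MCC"]]), 3), 0.503)
  expect_identical(unname(confusionCounts(rep)),
                   c(8L, 3L, 7L, 2L))
})

test_that("MCC returns 0 when a denominator factor vanishes", {
  d <- countsToVectors(5, 5, 0, 0)  # TN + FN = 0
  expect_equal(unname(metricValues(
    classificationMetrics(d$truth, d$calls))[["MCC"]]), 0)
})

test_that("swapping the class labels swaps Sn/Sp and negates MCC", {
  d <- countsToVectors(8, 3, 7, 2)
  m1 <- metricValues(classificationMetrics(d$truth, d$calls))
  swap <- function(v) ifelse(v == "binding", "non-binding", "binding")
  m2 <- metricValues(classificationMetrics(swap(d$truth), swap(d$calls)))
  expect_equal(unname(m2[["Sn"]]), unname(m1[["Sp"]]))
  expect_equal(unname(m2[["Sp"]]), unname(m1[["Sn"]]))
  expect_equal(unname(m2[["MCC"]]), unname(m1[["MCC"]]))  # symmetric here
  # negation shows when only the truth flips
  m3 <- metricValues(classificationMetrics(swap(d$truth), d$calls))
  expect_equal(unname(m3[["MCC"]]), -unname(m1[["MCC"]]))
})

test_that("auROC equals the exhaustive pairwise oracle and handles extremes", {
  truth <- rep(c("binding", "non-binding"), each = 5)
  expect_equal(aurocScore(truth, c(6:10, 1:5)), 1)
  expect_equal(aurocScore(truth, c(1:5, 6:10)), 0)
  set.seed(91)
  for (i in 1:50) {
    n <- sample(6:20, 1)
    labels <- sample(rep(c("binding", "non-binding"), c(3, n - 3)))
    scores <- round(rnorm(n), 1)  # rounding forces ties
    expect_equal(aurocScore(labels, scores),
                 pairwiseAuroc(labels, scores))
  }
  expect_error(aurocScore(rep("binding", 4), rnorm(4)), "both classes")
})

test_that("auROC is invariant under strictly increasing score transforms", {
  set.seed(92)
  labels <- sample(rep(c("binding", "non-binding"), each = 10))
  scores <- rnorm(20)
  a <- aurocScore(labels, scores)
  expect_equal(aurocScore(labels, exp(scores)), a)
  expect_equal(aurocScore(labels, 3 * scores + 7), a)
})

test_that("auROC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(93)
  labels <- sample(rep(c("binding", "non-binding"), c(12, 15)))
  scores <- rnorm(27)
  ours <- aurocScore(labels, scores)
  theirs <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores, levels = c("non-binding",
    "binding"), direction = "<", quiet = TRUE)))
  expect_equal(ours, theirs)
})

test_that("ROC curves run from (0,0) to (1,1) monotonically; perfect auPR is 1", {
  set.seed(94)
  labels <- sample(rep(c("binding", "non-binding"), each = 8))
  scores <- rnorm(16)
  roc <- rocCurve(labels, scores)
  expect_equal(unlist(roc[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(roc[nrow(roc), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
  truth <- rep(c("binding", "non-binding"), each = 5)
  expect_equal(auprScore(truth, c(6:10, 1:5)), 1)
  expect_true(auprScore(truth, c(1:5, 6:10)) < 0.5)
})

test_that("jackknife is deterministic and equals leave-one-out k-fold", {
  coll <- generateCollection(nPos = 6, nNeg = 6, lengthRange = c(25, 40),
                             effect = 3, seed = 95)
  x <- featureTable(coll)
  y <- collectionLabels(coll)
  j1 <- jackknifeCV(x, y, k = 5, rfeStep = 0.3)
  j2 <- jackknifeCV(x, y, k = 5, rfeStep = 0.3)
  expect_equal(metricValues(j1), metricValues(j2))
  expect_equal(sum(confusionCounts(j1)), nrow(x))
  cv <- kfoldCV(x, y, k = 5, folds = nrow(x), repeats = 1, seed = 7,
                rfeStep = 0.3)
  expect_equal(unname(cv$metrics), unname(metricValues(j1)))
})

test_that("item order does not change pooled metrics", {
  coll <- generateCollection(nPos = 5, nNeg = 5, lengthRange = c(25, 40),
                             effect = 3, seed = 96)
  x <- featureTable(coll)
  y <- collectionLabels(coll)
  perm <- sample(nrow(x))
  j1 <- jackknifeCV(x, y, k = 4, rfeStep = 0.3)
  j2 <- jackknifeCV(x[perm, ], y[perm], k = 4, rfeStep = 0.3)
  expect_equal(metricValues(j1), metricValues(j2))
})

test_that("cross-validation rejects impossible fold requests", {
  coll <- generateCollection(nPos = 3, nNeg = 3, lengthRange = c(25, 30),
                             effect = 0, seed = 97)
  x <- featureTable(coll)
  y <- collectionLabels(coll)
  expect_error(kfoldCV(x, y, folds = 1), "at least 2")
  expect_error(kfoldCV(x, y, folds = 7, k = 5), "too few")
})
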