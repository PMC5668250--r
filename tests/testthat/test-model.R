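separableData <- function(n = 20, p = 4, gap = 3, seed = 81) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n / 2 * p, -gap / 2), n / 2, p),
             matrix(rnorm(n / 2 * p, gap / 2), n / 2, p))
  y <- factor(rep(c("non-binding", "binding"), each = n / 2),
              levels = c("non-binding", "binding"))
  list(x = x, y = y)
}

test_that("kernels evaluate their closed forms and are symmetric", {
  expect_equal(kernelEval(c(1, 1), c(1, 1), "linear"), 2)
  expect_equal(kernelEval(1:5, 1:5, "rbf", gamma = 0.3), 1)
  expect_equal(kernelEval(c(1, -1), c(1, 1), "sigmoid", gamma = 1, r = 0),
               tanh(0))
  set.seed(82)
  for (i in 1:20) {
    x <- rnorm(6); y <- rnorm(6); g <- runif(1, 0.01, 2)
    expect_equal(kernelEval(x, y, "linear"), kernelEval(y, x, "linear"))
    expect_equal(kernelEval(x, y, "rbf", g), kernelEval(y, x, "rbf", g))
    expect_equal(kernelEval(x, y, "sigmoid", g, r = 0.5),
                 kernelEval(y, x, "sigmoid", g, r = 0.5))
    expect_gt(kernelEval(x, y, "rbf", g), 0)
    expect_lte(kernelEval(x, y, "rbf", g), 1)
    expect_lt(abs(kernelEval(x, y, "sigmoid", g)), 1)
    expect_equal(kernelEval(x, y, "rbf", g),
                 exp(-g * sum((x - y)^2)))
  }
  expect_error(kernelEval(1:3, 1:4, "linear"), "equal length")
  expect_error(kernelEval(1:3, 1:3, "rbf", gamma = -1), "gamma")
})

test_that("a linearly separable toy set is fit to training accuracy 1", {
  d <- separableData()
  m <- trainBindingModel(d$x, d$y)
  pr <- predict(m, d$x)
  expect_equal(mean(pr$label == as.character(d$y)), 1)
  expect_true(all((pr$score > 0) == (d$y == "binding")))
})

test_that("flipping the labels negates the decision scores", {
  d <- separableData(seed = 83)
  m1 <- trainBindingModel(d$x, d$y)
  flipped <- factor(ifelse(d$y == "binding", "non-binding", "binding"),
                    levels = c("non-binding", "binding"))
  m2 <- trainBindingModel(d$x, flipped)
  expect_equal(predict(m1, d$x)$score, -predict(m2, d$x)$score,
               tolerance = 1e-6)
})

test_that("duplicating every row preserves the decision boundary direction", {
  d <- separableData(seed = 84)
  m1 <- trainBindingModel(d$x, d$y)
  m2 <- trainBindingModel(rbind(d$x, d$x), c(as.character(d$y),
                                             as.character(d$y)))
  s1 <- predict(m1, d$x)$score
  s2 <- predict(m2, d$x)$score
  expect_true(all(sign(s1) == sign(s2)))
  expect_gt(stats::cor(s1, s2), 0.99)
})

test_that("batch prediction equals per-item prediction", {
  d <- separableData(seed = 85)
  m <- trainBindingModel(d$x, d$y, kernel = "rbf", gamma = 0.1)
  batch <- predict(m, d$x)
  single <- vapply(seq_len(nrow(d$x)), function(i)
    predict(m, d$x[i, ])$score, numeric(1))
  expect_equal(batch$score, single)
})

test_that("training rejects degenerate inputs with clear errors", {
  d <- separableData(seed = 86)
  expect_error(trainBindingModel(d$x, rep("binding", 20)), "both classes")
  bad <- d$x; bad[3, 2] <- NaN
  expect_error(trainBindingModel(bad, d$y), "column 2")
})

test_that("prediction accepts full or reduced layouts and rejects others", {
  set.seed(87)
  x <- matrix(rnorm(30 * 12), 30, 12)
  colnames(x) <- paste0("f", 1:12)
  y <- factor(rep(c("non-binding", "binding"), 15),
              levels = c("non-binding", "binding"))
  x[y == "binding", 5] <- x[y == "binding", 5] + 4
  m <- trainBindingModel(x, y, k = 3)
  full <- predict(m, x)
  reduced <- predict(m, applySelection(x, m@selection))
  expect_equal(full$score, reduced$score)
  expect_error(predict(m, x[, 1:7]), "layout mismatch")
})

test_that("models survive a save/load round trip with identical scores", {
  d <- separableData(seed = 88)
  m <- trainBindingModel(d$x, d$y, k = 2)
  f <- tempfile(fileext = ".rds")
  saveModel(m, f)
  m2 <- loadModel(f)
  set.seed(89)
  probe <- matrix(rnorm(100 * 4), 100, 4)
  expect_identical(predict(m2, probe)$score, predict(m, probe)$score)
  expect_identical(m2@selection@k, 2L)
  # corrupt / empty streams are refused
  empty <- tempfile(); file.create(empty)
  expect_error(loadModel(empty), "missing or empty")
  junk <- tempfile(); saveRDS(list(a = 1), junk)
  expect_error(loadModel(junk), "container")
  writeLines("not rds", junk)
  expect_error(loadModel(junk), "corrupt|container")
})
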