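## Performance metrics, ROC/PR curves, repeated stratified k-fold
## cross-validation and jackknife testing of the full pipeline.

#' Classification metrics from labels, calls and scores
#'
#' Computes sensitivity `TP / (TP + FN)`, specificity `TN / (TN + FP)`,
#' accuracy `(TP + TN) / total` and the Matthews correlation coefficient
#' `((TP * TN) - (FP * FN)) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))` from a
#' set of predictions, plus the ROC and precision-recall areas when
#' scores are supplied. When any factor of the MCC denominator is zero
#' the coefficient is reported as 0 (the formula is undefined there;
#' this convention keeps degenerate predictors at chance level).
#'
#' @param labels True labels (`binding` / `non-binding`, 1/0, or a
#'   two-level factor whose second level is positive).
#' @param predictions Predicted labels in the same encoding.
#' @param scores Optional numeric decision scores (larger = more
#'   binding-like) for the ROC/PR areas.
#' @return A [MetricsReport-class].
#' @examples
#' truth <- rep(c("binding", "non-binding"), c(10, 10))
#' calls <- rep(c("binding", "non-binding"), c(8, 12))  # 2 misses
#' metricValues(classificationMetrics(truth, calls))
#' @export
classificationMetrics <- function(labels, predictions, scores = NULL) {
  y <- .asBindingFactor(labels)
  yhat <- .asBindingFactor(predictions)
  if (length(y) == 0L) stop("empty input")
  if (length(y) != length(yhat))
    stop("labels and predictions must have equal length")
  tp <- sum(y == "binding" & yhat == "binding")
  fp <- sum(y == "non-binding" & yhat == "binding")
  tn <- sum(y == "non-binding" & yhat == "non-binding")
  fn <- sum(y == "binding" & yhat == "non-binding")
  sn <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / length(y)
  denom <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (denom == 0) 0 else ((tp * tn) - (fp * fn)) / denom
  auroc <- if (is.null(scores)) NA_real_ else aurocScore(y, scores)
  aupr <- if (is.null(scores)) NA_real_ else auprScore(y, scores)
  new("MetricsReport", sn = sn, sp = sp, acc = acc, mcc = mcc,
      auroc = auroc, aupr = aupr,
      counts = c(TP = as.integer(tp), FP = as.integer(fp),
                 TN = as.integer(tn), FN = as.integer(fn)))
}

#' Area under the ROC curve
#'
#' The probability that a uniformly drawn positive outscores a uniformly
#' drawn negative, with ties counted half (the Mann-Whitney statistic).
#' This equals trapezoidal integration of the ROC curve over all score
#' thresholds, and is invariant to any strictly increasing transform of
#' the scores.
#'
#' @param labels Binary labels (see [classificationMetrics()]).
#' @param scores Numeric scores, larger = more binding-like.
#' @return A number in \[0, 1\].
#' @export
aurocScore <- function(labels, scores) {
  y <- .asBindingFactor(labels)
  if (length(y) != length(scores))
    stop("labels and scores must have equal length")
  n_pos <- sum(y == "binding")
  n_neg <- sum(y == "non-binding")
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present to compute an ROC area")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == "binding"]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Trapezoidal integration of precision against recall over all score
#' thresholds, descending from the strictest threshold; the curve is
#' anchored at recall 0 with the precision of the first threshold.
#'
#' @inheritParams aurocScore
#' @return A number in \[0, 1\].
#' @export
auprScore <- function(labels, scores) {
  y <- .asBindingFactor(labels)
  if (length(y) != length(scores))
    stop("labels and scores must have equal length")
  n_pos <- sum(y == "binding")
  if (n_pos == 0L || n_pos == length(y))
    stop("both classes must be present to compute a PR area")
  ord <- order(scores, decreasing = TRUE)
  pos <- y[ord] == "binding"
  # group tied scores: evaluate at the last index of each tie block
  idx <- which(!duplicated(scores[ord], fromLast = TRUE))
  tp <- cumsum(pos)[idx]
  n_called <- idx
  recall <- tp / n_pos
  precision <- tp / n_called
  recall <- c(0, recall)
  precision <- c(precision[1L], precision)
  sum(diff(recall) * (utils::head(precision, -1) + utils::tail(precision, -1)) / 2)
}

#' ROC curve points
#'
#' The (false-positive-rate, true-positive-rate) pairs obtained by
#' sweeping the decision threshold across the unique score values, from
#' (0, 0) to (1, 1); tied scores form a single point.
#'
#' @inheritParams aurocScore
#' @return data.frame with columns `fpr` and `tpr`, both non-decreasing.
#' @export
rocCurve <- function(labels, scores) {
  y <- .asBindingFactor(labels)
  n_pos <- sum(y == "binding")
  n_neg <- sum(y == "non-binding")
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  pos <- y[ord] == "binding"
  idx <- which(!duplicated(scores[ord], fromLast = TRUE))
  data.frame(fpr = c(0, cumsum(!pos)[idx] / n_neg),
             tpr = c(0, cumsum(pos)[idx] / n_pos))
}

.stratifiedFolds <- function(y, folds) {
  fold_of <- integer(length(y))
  for (cl in levels(y)) {
    members <- sample(which(y == cl))
    fold_of[members] <- rep_len(seq_len(folds), length(members))
  }
  fold_of
}

.cvOnce <- function(x, y, folds, k, C, kernel, gamma, r, rfeStep,
                    shuffleFolds = TRUE) {
  fold_of <- if (shuffleFolds) .stratifiedFolds(y, folds)
             else rep_len(seq_len(folds), length(y))
  scores <- numeric(length(y))
  calls <- character(length(y))
  for (f in seq_len(folds)) {
    test <- which(fold_of == f)
    if (length(test) == 0L) next
    m <- trainBindingModel(x[-test, , drop = FALSE], y[-test],
                           kernel = kernel, C = C, gamma = gamma, r = r,
                           k = k, rfeStep = rfeStep)
    pr <- predict(m, x[test, , drop = FALSE])
    scores[test] <- pr$score
    calls[test] <- pr$label
  }
  report <- classificationMetrics(y, calls, scores)
  attr(report, "scores") <- scores
  attr(report, "labels") <- y
  report
}

#' Repeated stratified k-fold cross-validation of the full pipeline
#'
#' Evaluates the extract-select-train pipeline by stratified k-fold
#' cross-validation, repeated with fresh random splits, reporting the
#' mean of each metric over the repeats together with its spread. Within
#' every training fold the pipeline is fit from scratch — feature
#' standardization, recursive feature elimination and the classifier all
#' see the training folds only — so no information from a held-out fold
#' leaks into its own predictor. Setting `globalSelection = TRUE` instead runs
#' the selection once on the complete table before splitting, the
#' protocol in which tuned features are homogeneous with the evaluation
#' items; it is provided for comparison and is knowably optimistic
#' (demonstrably so on label-shuffled data).
#'
#' @param x Numeric n x p feature table, e.g. from [featureTable()].
#' @param y Binary labels (see [classificationMetrics()]).
#' @param k Number of features to keep by RFE, or NULL to skip
#'   selection. Default 86, the method's reduced feature count.
#' @param folds Number of folds (default 10).
#' @param repeats Number of repeated splits averaged over (default 50,
#'   the method's reporting convention; smaller values are appropriate
#'   for quick checks).
#' @param seed Integer seed governing all splits.
#' @param C,kernel,gamma,r Classifier settings, see
#'   [trainBindingModel()].
#' @param rfeStep Elimination granularity, see [rfeSelect()].
#' @param globalSelection If TRUE, perform one global selection before the
#'   folds instead of per-fold selection.
#' @return A `CvResult` list with elements `metrics` (mean over
#'   repeats), `sd`, `reports` (per-repeat [MetricsReport-class]),
#'   `folds`, `repeats`.
#' @export
kfoldCV <- function(x, y, k = 86L, folds = 10L, repeats = 50L, seed = 1L,
                    C = 1000, kernel = "linear", gamma = 0.01, r = 0,
                    rfeStep = 1L, globalSelection = FALSE) {
  x <- as.matrix(x)
  y <- .asBindingFactor(y)
  if (folds < 2L) stop("'folds' must be at least 2")
  if (min(table(y)) < 1L || length(y) < folds)
    stop("too few items for the requested number of folds")
  set.seed(seed)
  if (globalSelection && !is.null(k)) {
    sel <- rfeSelect(x, y, k = k, C = C, step = rfeStep)
    x <- applySelection(x, sel)
    k <- NULL
  }
  reports <- lapply(seq_len(repeats), function(i)
    .cvOnce(x, y, folds, k, C, kernel, gamma, r, rfeStep))
  vals <- do.call(rbind, lapply(reports, metricValues))
  out <- list(metrics = colMeans(vals), sd = apply(vals, 2L, stats::sd),
              reports = reports, folds = folds, repeats = repeats)
  class(out) <- "CvResult"
  out
}

#' @export
print.CvResult <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation, %d repeat(s)\n", x$folds,
              x$repeats))
  for (nm in names(x$metrics))
    cat(sprintf("  %-5s %.4f (sd %.4f)\n", nm, x$metrics[nm], x$sd[nm]))
  invisible(x)
}

#' Jackknife (leave-one-out) evaluation
#'
#' Predicts every protein from a model trained on all the others,
#' including per-fold standardization and feature selection. The
#' jackknife is deterministic: it has no random split, so repeated runs
#' give identical reports. Equivalent to [kfoldCV()] with `folds = n`
#' and a single repeat.
#'
#' @inheritParams kfoldCV
#' @return A [MetricsReport-class] over the n held-out predictions.
#' @export
jackknifeCV <- function(x, y, k = 86L, C = 1000, kernel = "linear",
                        gamma = 0.01, r = 0, rfeStep = 1L) {
  x <- as.matrix(x)
  y <- .asBindingFactor(y)
  if (min(table(y)) < 2L)
    stop("jackknife needs at least two items per class")
  .cvOnce(x, y, folds = nrow(x), k = k, C = C, kernel = kernel,
          gamma = gamma, r = r, rfeStep = rfeStep, shuffleFolds = FALSE)
}
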