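## Recursive feature elimination under a linear maximum-margin ranker.

.standardizeFit <- function(x, varFloor = 1e-8) {
  center <- colMeans(x)
  sds <- apply(x, 2L, stats::sd)
  sds[!is.finite(sds) | sds < varFloor] <- 1  # zero-variance guard
  list(center = center, scaleSd = sds)
}

.standardizeApply <- function(x, std) {
  sweep(sweep(x, 2L, std$center, "-"), 2L, std$scaleSd, "/")
}

.linearSvmWeights <- function(x, y, C, tol) {
  fit <- e1071::svm(x, y, kernel = "linear", cost = C, scale = FALSE,
                    tolerance = tol)
  w <- crossprod(fit$coefs, fit$SV)
  as.numeric(w)
}

#' Recursive feature elimination
#'
#' Starting from the full feature table, repeatedly fits a linear
#' maximum-margin classifier on the surviving columns, ranks the columns
#' by squared hyperplane weight, and removes the lowest-ranked column,
#' until `k` columns remain. Because features leave one at a time, the
#' selections are nested: the `k = 50` set is a subset of the `k = 100`
#' set from the same data.
#'
#' Columns are standardized internally (mean 0, unit variance, computed
#' on `x` itself) before any fit: coefficient magnitudes are not
#' comparable across raw blocks with heterogeneous scales (counts versus
#' probabilities). A variance floor guards constant columns. The
#' procedure is deterministic given the data and parameters.
#'
#' @param x Numeric n x p feature matrix (rows = proteins).
#' @param y Binary labels: a factor or a vector coercible to one with
#'   two observed classes.
#' @param k Target number of surviving features, `1 <= k <= p`.
#' @param C Soft-margin constant of the linear ranker (default 1000,
#'   matching the final classifier).
#' @param step Elimination granularity: 1 (the default) removes exactly
#'   one feature per refit; an integer > 1 removes that many per refit;
#'   a fraction in (0, 1) removes that share of the remaining columns
#'   (at least one) per refit — a speed option that trades ranking
#'   resolution for fewer fits. Nesting across `k` is only guaranteed at
#'   `step = 1`.
#' @param tol Solver tolerance of the underlying SVM (default 1e-4).
#' @return A [RankedFeatureSet-class].
#' @examples
#' set.seed(7)
#' x <- matrix(rnorm(200), 20, 10)
#' y <- factor(rep(c("a", "b"), each = 10))
#' x[y == "b", 3] <- x[y == "b", 3] + 5
#' selectedFeatures(rfeSelect(x, y, k = 1))
#' @export
rfeSelect <- function(x, y, k, C = 1000, step = 1L, tol = 1e-4) {
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(droplevels(y)) != 2L)
    stop("both classes must be present in 'y'")
  y <- droplevels(y)
  p <- ncol(x)
  k <- as.integer(k)
  if (k < 1L || k > p)
    stop(sprintf("'k' must lie between 1 and the number of columns (%d)", p))
  if (is.numeric(step) && step > 0 && step < 1) {
    frac <- step
    stepFun <- function(remaining) max(1L, as.integer(floor(frac * remaining)))
  } else {
    step <- as.integer(step)
    if (is.na(step) || step < 1L) stop("'step' must be >= 1 or a fraction in (0, 1)")
    stepFun <- function(remaining) step
  }
  std <- .standardizeFit(x)
  xs <- .standardizeApply(x, std)

  alive <- seq_len(p)
  elim_index <- integer(0)
  elim_iter <- integer(0)
  iter <- 0L
  while (length(alive) > k) {
    iter <- iter + 1L
    w <- .linearSvmWeights(xs[, alive, drop = FALSE], y, C = C, tol = tol)
    ranking <- order(w^2)  # ascending: weakest first
    n_drop <- min(stepFun(length(alive)), length(alive) - k)
    drop_local <- ranking[seq_len(n_drop)]
    elim_index <- c(elim_index, alive[drop_local])
    elim_iter <- c(elim_iter, rep(iter, n_drop))
    alive <- alive[-drop_local]
  }
  new("RankedFeatureSet",
      selected = sort(alive),
      eliminationOrder = data.frame(index = elim_index,
                                    iteration = elim_iter),
      k = k, nFeatures = p,
      featureNames = if (is.null(colnames(x))) character(0) else colnames(x))
}

#' Restrict a feature table to a selection
#'
#' Keeps only the columns chosen by a [RankedFeatureSet-class], in their
#' original order.
#'
#' @param x Numeric feature matrix with the same layout (column count,
#'   and names when present) as the table the selection was derived from.
#' @param rfs A [RankedFeatureSet-class].
#' @return The reduced matrix with `length(selectedFeatures(rfs))`
#'   columns.
#' @export
applySelection <- function(x, rfs) {
  stopifnot(is(rfs, "RankedFeatureSet"))
  x <- as.matrix(x)
  if (ncol(x) != rfs@nFeatures)
    stop(sprintf("layout mismatch: selection expects %d columns, got %d",
                 rfs@nFeatures, ncol(x)))
  if (length(rfs@featureNames) && !is.null(colnames(x)) &&
      !identical(colnames(x), rfs@featureNames))
    stop("layout mismatch: column names differ from the selection's source")
  x[, rfs@selected, drop = FALSE]
}
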