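## Kernels, classifier training, prediction and model persistence.

.MODEL_VERSION <- 1L

#' Evaluate a kernel function
#'
#' The three kernels of the classifier, as explicit formulas:
#' linear `K(x, y) = x . y`; RBF `K(x, y) = exp(-gamma * ||x - y||^2)`;
#' sigmoid `K(x, y) = tanh(gamma * (x . y) + r)`. All are symmetric; RBF
#' values lie in (0, 1\] and sigmoid values in (-1, 1).
#'
#' @param x,y Numeric vectors of equal length.
#' @param kernel One of `"linear"`, `"rbf"`, `"sigmoid"`.
#' @param gamma Kernel width, required > 0 for rbf and sigmoid; ignored
#'   for linear.
#' @param r Sigmoid offset (default 0); ignored otherwise.
#' @return A single number.
#' @examples
#' kernelEval(c(1, 1), c(1, 1), "linear")       # 2
#' kernelEval(1:3, 1:3, "rbf", gamma = 0.5)     # 1
#' @export
kernelEval <- function(x, y, kernel = c("linear", "rbf", "sigmoid"),
                       gamma = 0.01, r = 0) {
  kernel <- match.arg(kernel)
  if (length(x) != length(y))
    stop("kernel arguments must have equal length")
  if (kernel != "linear" && (!is.numeric(gamma) || gamma <= 0))
    stop("'gamma' must be > 0 for the rbf and sigmoid kernels")
  switch(kernel,
    linear = sum(x * y),
    rbf = exp(-gamma * sum((x - y)^2)),
    sigmoid = tanh(gamma * sum(x * y) + r))
}

#' Train the DNA-binding classifier
#'
#' Fits a soft-margin support vector machine on standardized features,
#' optionally after recursive feature elimination. The method's settings
#' are the defaults: linear kernel with C = 1000 (gamma = 0.01 is stored
#' alongside but is inert for the linear kernel). Standardization
#' parameters are learned on the training data and stored in the model,
#' so prediction accepts raw-unit feature vectors. No class weighting is
#' applied by default (the reference benchmark is near-balanced); pass
#' `classWeights` to compensate imbalanced collections.
#'
#' @param x Numeric n x p feature matrix (rows = proteins), e.g. from
#'   [featureTable()].
#' @param y Labels: factor or character with values `binding` /
#'   `non-binding` (0/1 and generic two-level factors are accepted; the
#'   second level is treated as the positive class).
#' @param kernel `"linear"` (default), `"rbf"` or `"sigmoid"`.
#' @param C Soft-margin constant (default 1000).
#' @param gamma Kernel width (default 0.01).
#' @param r Sigmoid offset (default 0).
#' @param k If non-NULL, run [rfeSelect()] to `k` features on the
#'   standardized training data before fitting.
#' @param rfeStep Elimination granularity passed to [rfeSelect()].
#' @param classWeights Optional named weights for the two classes.
#' @return A [BindingModel-class].
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(40, -1), 10), matrix(rnorm(40, 1), 10))
#' y <- rep(c("non-binding", "binding"), each = 10)
#' m <- trainBindingModel(x, y)
#' predict(m, x)$label
#' @export
trainBindingModel <- function(x, y, kernel = c("linear", "rbf", "sigmoid"),
                              C = 1000, gamma = 0.01, r = 0, k = NULL,
                              rfeStep = 1L, classWeights = NULL) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  if (any(!is.finite(x))) {
    bad <- which(apply(x, 2L, function(col) any(!is.finite(col))))[1L]
    stop(sprintf("feature column %d ('%s') contains non-finite values",
                 bad, colnames(x)[bad] %||% ""))
  }
  y <- .asBindingFactor(y)
  if (nlevels(droplevels(y)) != 2L)
    stop("both classes must be present to train a classifier")

  std <- .standardizeFit(x)
  xs <- .standardizeApply(x, std)
  selection <- NULL
  if (!is.null(k)) {
    selection <- rfeSelect(x, y, k = k, C = C, step = rfeStep)
    xs <- xs[, selection@selected, drop = FALSE]
  }
  svm_kernel <- switch(kernel, linear = "linear", rbf = "radial",
                       sigmoid = "sigmoid")
  fit <- e1071::svm(xs, y, kernel = svm_kernel, cost = C, gamma = gamma,
                    coef0 = r, scale = FALSE, class.weights = classWeights)
  # libsvm orients its decision values toward whichever class it saw
  # first; fix the orientation so that positive scores mean binding
  dv <- attr(stats::predict(fit, xs, decision.values = TRUE),
             "decision.values")[, 1L]
  pred <- stats::predict(fit, xs)
  agree <- mean(sign(dv)[pred == "binding"] > 0)
  orientation <- if (!is.nan(agree) && agree < 0.5) -1 else 1

  new("BindingModel", fit = fit, kernel = kernel, cost = C, gamma = gamma,
      coef0 = r, center = std$center, scaleSd = std$scaleSd,
      selection = selection,
      featureNames = if (is.null(colnames(x))) character(0) else colnames(x),
      orientation = orientation, version = .MODEL_VERSION)
}

`%||%` <- function(a, b) {
  if (is.null(a) || length(a) == 0L || (length(a) == 1L && is.na(a))) b else a
}

.asBindingFactor <- function(y) {
  if (is.factor(y) && identical(levels(y), c("non-binding", "binding")))
    return(y)
  y <- as.character(y)
  y[y == "1"] <- "binding"
  y[y == "0"] <- "non-binding"
  if (!all(y %in% c("binding", "non-binding")))
    stop("labels must be binding/non-binding (or 1/0)")
  factor(y, levels = c("non-binding", "binding"))
}

#' Predict DNA binding for new proteins
#'
#' Applies the stored standardization and feature selection to raw
#' feature vectors and returns the signed decision value of the trained
#' classifier; a protein is called `binding` iff its score is positive.
#' Full-layout vectors are reduced automatically when the model holds a
#' selection. Batch prediction equals row-by-row prediction.
#'
#' @param object A [BindingModel-class].
#' @param newdata Numeric matrix (rows = proteins) or a single feature
#'   vector, in the model's input layout (full layout or, alternatively,
#'   already reduced to the selected columns).
#' @param ... Ignored.
#' @return A data.frame with columns `id` (row names when present),
#'   `label` and `score`.
#' @export
setMethod("predict", "BindingModel", function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  p_full <- length(object@center)
  sel <- object@selection
  if (ncol(newdata) == p_full) {
    xs <- .standardizeApply(newdata, list(center = object@center,
                                          scaleSd = object@scaleSd))
    if (!is.null(sel)) xs <- xs[, sel@selected, drop = FALSE]
  } else if (!is.null(sel) && ncol(newdata) == sel@k) {
    xs <- .standardizeApply(newdata, list(
      center = object@center[sel@selected],
      scaleSd = object@scaleSd[sel@selected]))
  } else {
    stop(sprintf("layout mismatch: model expects %d (or %d selected) columns, got %d",
                 p_full, if (is.null(sel)) p_full else sel@k, ncol(newdata)))
  }
  dv <- attr(stats::predict(object@fit, xs, decision.values = TRUE),
             "decision.values")[, 1L]
  score <- object@orientation * dv
  data.frame(id = rownames(newdata) %||% as.character(seq_len(nrow(xs))),
             label = ifelse(score > 0, "binding", "non-binding"),
             score = unname(score), row.names = NULL,
             stringsAsFactors = FALSE)
})

#' Persist and restore a trained model
#'
#' `saveModel` serializes a [BindingModel-class] (with its
#' standardization, selection and kernel settings) to a versioned
#' container file; `loadModel` restores it. A restored model reproduces
#' the saved model's decision scores exactly.
#'
#' @param m A [BindingModel-class].
#' @param file Path of the model container.
#' @return `saveModel`: the path, invisibly. `loadModel`: the model.
#' @export
saveModel <- function(m, file) {
  stopifnot(is(m, "BindingModel"))
  saveRDS(list(format = "DNABindProfiles-model", version = m@version,
               model = m), file)
  invisible(file)
}

#' @rdname saveModel
#' @export
loadModel <- function(file) {
  if (!file.exists(file) || file.size(file) == 0L)
    stop("model file is missing or empty")
  obj <- tryCatch(readRDS(file), error = function(e)
    stop("corrupt model file: ", conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$format, "DNABindProfiles-model"))
    stop("not a DNABindProfiles model container")
  if (!identical(obj$version, .MODEL_VERSION))
    stop(sprintf("model format version %s is not supported (expected %d)",
                 obj$version %||% "?", .MODEL_VERSION))
  obj$model
}
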