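## Generic profile-matrix operators shared by the evolutionary and
## structural feature layers. All operate on plain numeric L x W matrices
## and return named vectors in a fixed, documented order.

.checkProfileMatrix <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 1L || ncol(X) < 1L)
    stop("profile matrix must have at least one row and one column")
  if (any(!is.finite(X)))
    stop("profile matrix entries must be finite")
  X
}

.colTag <- function(X) {
  if (!is.null(colnames(X))) colnames(X) else paste0("c", seq_len(ncol(X)))
}

#' Column-wise composition of a profile matrix
#'
#' The length-normalized column sums of an L x W profile matrix:
#' `out[j] = sum(X[, j]) / L`. The sum runs over all L rows.
#'
#' @param X Numeric L x W matrix with finite entries.
#' @return Named numeric vector of length W.
#' @examples
#' profileComposition(rbind(c(1, 0), c(0, 1)))
#' @export
profileComposition <- function(X) {
  X <- .checkProfileMatrix(X)
  stats::setNames(colSums(X) / nrow(X), .colTag(X))
}

#' Lagged bigram of a profile matrix
#'
#' Transition products between profile rows separated by `lag` positions:
#' `out[(k, l)] = sum_{i=1..L-lag} X[i, k] * X[i+lag, l] / L`, flattened
#' row-major over the column pair (k, l). The denominator is L, not
#' L - lag, matching the defining formulas; this slightly shrinks values
#' for short sequences.
#'
#' @param X Numeric L x W matrix.
#' @param lag Positive integer separation; `lag = 1` pairs adjacent rows.
#' @return Named numeric vector of length W^2.
#' @examples
#' profileBigram(rbind(c(1, 0), c(0, 1)), lag = 1)
#' @export
profileBigram <- function(X, lag = 1L) {
  X <- .checkProfileMatrix(X)
  lag <- as.integer(lag)
  if (lag < 1L) stop("'lag' must be a positive integer")
  L <- nrow(X)
  if (L <= lag)
    stop(sprintf("bigram with lag %d needs at least %d rows, got %d",
                 lag, lag + 1L, L))
  head_rows <- X[seq_len(L - lag), , drop = FALSE]
  tail_rows <- X[seq_len(L - lag) + lag, , drop = FALSE]
  B <- crossprod(head_rows, tail_rows) / L
  tags <- .colTag(X)
  out <- as.vector(t(B))  # row-major over (k, l)
  names(out) <- paste(rep(tags, each = ncol(X)), rep(tags, ncol(X)),
                      sep = "_")
  out
}

#' Auto-covariance of a profile matrix
#'
#' Same-column lagged products up to a distance factor `df`:
#' `out[(j, k)] = sum_{i=1..L-k} X[i, j] * X[i+k, j] / L` for lags
#' k = 1..df, flattened with lag varying fastest within each column.
#' Equals the diagonal (j, j) of [profileBigram()] at each lag.
#'
#' @param X Numeric L x W matrix.
#' @param df Positive integer distance factor (maximum lag); the method's
#'   default is 10.
#' @return Named numeric vector of length W * df.
#' @examples
#' profileAutoCovariance(matrix(c(1, 1, 0), ncol = 1), df = 2)
#' @export
profileAutoCovariance <- function(X, df = 10L) {
  X <- .checkProfileMatrix(X)
  df <- as.integer(df)
  if (df < 1L) stop("'df' must be a positive integer")
  L <- nrow(X)
  if (L <= df)
    stop(sprintf("auto-covariance with df %d needs at least %d rows, got %d",
                 df, df + 1L, L))
  tags <- .colTag(X)
  out <- numeric(ncol(X) * df)
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    for (k in seq_len(df)) {
      out[(j - 1L) * df + k] <-
        sum(v[seq_len(L - k)] * v[seq_len(L - k) + k]) / L
    }
  }
  names(out) <- paste(rep(tags, each = df), "lag", rep(seq_len(df), ncol(X)),
                      sep = "_")
  out
}

#' Segmented distribution of a profile matrix
#'
#' For each column, the normalized row positions at which the cumulative
#' column mass first reaches each percentage threshold p in
#' \{step, 2*step, ..., 50\}, measured from the top of the column and
#' (independently) from the bottom. From the top: the smallest i with
#' `sum(X[1:i, j]) >= p%` of the column total, divided by L. From the
#' bottom: the smallest count of trailing rows reaching p%, divided by L.
#' Values per column are ordered top thresholds ascending, then bottom
#' thresholds ascending; columns are outermost.
#'
#' Thresholds are scale-free: multiplying a column by any c > 0 leaves its
#' values unchanged.
#'
#' @param X Numeric L x W matrix whose columns each have a strictly
#'   positive total sum (the entries of a normalized PSSM are in (0, 1),
#'   so this holds there by construction).
#' @param stepPercent Threshold step in percent; must divide 50. The
#'   default 10 yields 2 * 5 = 10 values per column; 5 and 25 are the
#'   other conventional choices.
#' @return Named numeric vector of length `W * 2 * (50 / stepPercent)`,
#'   all values in (0, 1\].
#' @examples
#' segmentedDistribution(matrix(rep(1, 100), ncol = 1), stepPercent = 10)
#' @export
segmentedDistribution <- function(X, stepPercent = 10) {
  X <- .checkProfileMatrix(X)
  if (stepPercent <= 0 || stepPercent > 50 || (50 %% stepPercent) != 0)
    stop("'stepPercent' must lie in (0, 50] and divide 50")
  totals <- colSums(X)
  if (any(totals <= 0))
    stop("every column must have a strictly positive total sum")
  L <- nrow(X)
  thresholds <- seq(stepPercent, 50, by = stepPercent) / 100
  tags <- .colTag(X)
  per_col <- 2L * length(thresholds)
  out <- numeric(ncol(X) * per_col)
  nms <- character(length(out))
  for (j in seq_len(ncol(X))) {
    cs_top <- cumsum(X[, j])
    cs_bot <- cumsum(rev(X[, j]))
    tol <- 1e-12 * totals[j]
    top <- vapply(thresholds, function(p)
      which(cs_top >= p * totals[j] - tol)[1L] / L, numeric(1))
    bot <- vapply(thresholds, function(p)
      which(cs_bot >= p * totals[j] - tol)[1L] / L, numeric(1))
    idx <- (j - 1L) * per_col + seq_len(per_col)
    out[idx] <- c(top, bot)
    nms[idx] <- paste0(tags[j], "_",
                       rep(c("top", "bottom"), each = length(thresholds)),
                       rep(thresholds * 100, 2))
  }
  stats::setNames(out, nms)
}
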