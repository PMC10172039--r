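#' Binarize single-cell expression counts
#'
#' Dropout-aware binarization for single-cell data: every zero stays 0 and
#' every non-zero value becomes 1, regardless of magnitude. No imputation is
#' performed; the zero pattern itself is treated as signal.
#'
#' @param E numeric matrix, genes in rows, cells/time points in columns;
#'   entries must be nonnegative
#' @return integer 0/1 matrix of the same shape and dimnames
#' @export
binarizeSingleCell <- function(E) {
  E <- .asExpressionMatrix(E)
  B <- (E > 0) * 1L
  storage.mode(B) <- "integer"
  B
}

#' Binarize bulk expression profiles per gene
#'
#' Per-gene thresholding for continuous (bulk) profiles. `gene_mean` sets a
#' value to 1 iff it exceeds the gene's mean across time points; `kmeans2`
#' splits each gene's values into two clusters (initial centers at the gene
#' minimum and maximum, so the split is deterministic) and maps the
#' high-mean cluster to 1. A constant gene cannot be split and falls back
#' to an all-zero row with a warning.
#'
#' @param E numeric matrix, genes x time points (at least 2 columns)
#' @param method `"gene_mean"` (default) or `"kmeans2"`
#' @return integer 0/1 matrix of the same shape
#' @export
binarizeBulk <- function(E, method = c("gene_mean", "kmeans2")) {
  method <- match.arg(method)
  E <- .asExpressionMatrix(E)
  if (ncol(E) < 2L) stop("need at least 2 time points")
  B <- matrix(0L, nrow(E), ncol(E), dimnames = dimnames(E))
  for (i in seq_len(nrow(E))) {
    x <- E[i, ]
    if (method == "gene_mean") {
      B[i, ] <- as.integer(x > mean(x))
    } else {
      if (max(x) == min(x)) {
        warning("constant gene in row ", i, ": emitting all-zero row")
        next
      }
      km <- stats::kmeans(x, centers = c(min(x), max(x)))
      hi <- which.max(km$centers)
      B[i, ] <- as.integer(km$cluster == hi)
    }
  }
  B
}

#' Order expression columns by pseudo-time
#'
#' Sorts the columns of an expression (or binary) matrix ascending by a
#' pseudo-time vector; ties are broken by the original column index, so the
#' sort is stable and idempotent.
#'
#' @param E matrix with one column per cell/time point
#' @param pseudotime finite numeric vector, one value per column
#' @return the matrix with columns reordered
#' @export
orderByPseudotime <- function(E, pseudotime) {
  if (length(pseudotime) != ncol(E))
    stop("pseudotime length ", length(pseudotime),
         " != number of columns ", ncol(E))
  if (any(!is.finite(pseudotime)))
    stop("pseudotime must be finite")
  E[, order(pseudotime, seq_along(pseudotime)), drop = FALSE]
}

#' Build the per-gene regression design from a binary matrix
#'
#' For target gene i the design pairs are `(X(j), y(j))`, `j = 1..T-1`:
#' `X(j)` is the full network state at time j with an intercept 1 appended
#' (last column), and `y(j)` is gene i's state at time `j + 1`. The target
#' gene's own column is part of `X`, so self-regulation is representable.
#' All genes share the same `X`; only `y` differs.
#'
#' @param B integer 0/1 matrix, genes x time points, `T >= 3`
#' @param target index of the target gene
#' @return list with `X` (`(T-1) x (N+1)` with intercept last) and `y`
#'   (length `T-1` 0/1 vector)
#' @export
buildDesign <- function(B, target) {
  if (!all(B %in% c(0L, 1L))) stop("B must be a 0/1 matrix")
  T_ <- ncol(B)
  if (T_ < 3L) stop("insufficient time points: need T >= 3, got ", T_)
  if (target < 1L || target > nrow(B)) stop("target index out of range")
  X <- t(B[, seq_len(T_ - 1L), drop = FALSE])
  X <- cbind(X, `(Intercept)` = 1L)
  rownames(X) <- NULL
  y <- as.integer(B[target, 2:T_])
  list(X = X, y = y)
}

.asExpressionMatrix <- function(E) {
  E <- as.matrix(E)
  if (!is.numeric(E)) stop("expression matrix must be numeric")
  if (any(E < 0)) stop("expression matrix must be nonnegative")
  E
}

## strip an all-ones intercept column if the caller passed a full design
.stripIntercept <- function(X) {
  p <- ncol(X)
  if (p >= 2L && all(X[, p] == 1)) X[, -p, drop = FALSE] else X
}
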