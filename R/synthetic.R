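#' The nine-gene benchmark threshold network
#'
#' The fixed nine-node Boolean threshold network used throughout the
#' package's synthetic experiments. Its 25 directed signed edges (three of
#' them self-loops: x1, x5 and x8 regulate themselves) and mixed weights
#' (x7 and x8 carry non-unit weights) exercise every feature of the rule
#' representation.
#'
#' @return a [BooleanThresholdNetwork-class] with genes `x1..x9`
#' @examples
#' net <- exampleNetwork9()
#' length(net)                          # 9
#' sum(goldStandard9() != 0)            # 25 edges
#' @export
exampleNetwork9 <- function() {
  BooleanThresholdNetwork(list(
    ThresholdRule(c(1L, 2L), c(1, 1), c(FALSE, FALSE), 1),                      # x1
    ThresholdRule(c(1L, 4L, 5L, 9L), rep(1, 4), rep(TRUE, 4), 4),               # x2
    ThresholdRule(c(2L, 5L, 9L), rep(1, 3), rep(TRUE, 3), 3),                   # x3
    ThresholdRule(c(2L, 3L), c(1, 1), c(TRUE, FALSE), 2),                       # x4
    ThresholdRule(c(2L, 3L, 5L), c(1, 1, 1), c(TRUE, FALSE, FALSE), 3),         # x5
    ThresholdRule(9L, 1, FALSE, 1),                                             # x6
    ThresholdRule(c(5L, 6L, 9L), c(1, 2, 1), c(TRUE, FALSE, TRUE), 2),          # x7
    ThresholdRule(c(5L, 6L, 7L, 8L, 9L), c(1, 1, 5, 4, 1),
                  c(FALSE, FALSE, TRUE, FALSE, FALSE), 5),                      # x8
    ThresholdRule(c(6L, 7L), c(1, 1), c(TRUE, TRUE), 2)                         # x9
  ))
}

#' Signed gold-standard adjacency of the nine-gene network
#'
#' @return 9 x 9 matrix with entries in `{-1, 0, +1}`; entry `[k, i]` is the
#'   sign of regulator k's literal in gene i's rule
#' @export
goldStandard9 <- function() {
  goldFromNetwork(exampleNetwork9())
}

#' Signed adjacency matrix of a threshold network
#'
#' @param net a [BooleanThresholdNetwork-class]
#' @return N x N matrix in `{-1, 0, +1}` (regulator rows, target columns)
#' @export
goldFromNetwork <- function(net) {
  stopifnot(is(net, "BooleanThresholdNetwork"))
  n <- length(net)
  gold <- matrix(0L, n, n, dimnames = list(net@geneNames, net@geneNames))
  for (i in seq_len(n)) {
    r <- net@rules[[i]]
    gold[r@regulators, i] <- ifelse(r@negated, -1L, 1L)
  }
  gold
}

#' Flip-noise corruption of a binary matrix
#'
#' Complements each entry independently with probability `delta`.
#'
#' @param B 0/1 matrix
#' @param delta flip probability in \[0, 1\]
#' @param seed integer seed or NULL
#' @return corrupted 0/1 matrix of the same shape
#' @export
flipNoise <- function(B, delta, seed = NULL) {
  if (delta < 0 || delta > 1) stop("delta must be in [0, 1]")
  if (!all(B %in% c(0L, 1L))) stop("B must be a 0/1 matrix")
  out <- .withSeed(seed, {
    flips <- matrix(stats::runif(length(B)) < delta, nrow(B), ncol(B))
    (B + flips) %% 2
  })
  storage.mode(out) <- "integer"
  dimnames(out) <- dimnames(B)
  out
}

#' Generate the exhaustive-transition benchmark data set
#'
#' Enumerates all `2^9 = 512` states of the nine-gene network with their
#' synchronous successors, then (optionally) flips every entry of both the
#' state and the successor matrix independently with probability `delta`.
#' At `delta = 0` the data are noiseless and the network is exactly
#' recoverable.
#'
#' @param delta per-entry flip probability
#' @param seed integer seed or NULL
#' @param flipTargetsOnly corrupt only the successor matrix, leaving the
#'   input states clean (sensitivity option)
#' @return list with `X` (512 x 9 states), `Y` (512 x 9 successors),
#'   `gold` (signed adjacency) and `network`
#' @export
generateBenchmark <- function(delta = 0, seed = NULL, flipTargetsOnly = FALSE) {
  net <- exampleNetwork9()
  pairs <- enumerateStatePairs(net)
  X <- pairs$states
  Y <- pairs$successors
  if (delta > 0) {
    if (!flipTargetsOnly)
      X <- flipNoise(X, delta, seed = .deriveSeed(seed, 1L))
    Y <- flipNoise(Y, delta, seed = .deriveSeed(seed, 2L))
  }
  list(X = X, Y = Y, gold = goldStandard9(), network = net)
}

#' Subsample paired observations
#'
#' Uniform sample of rows without replacement, keeping (state, successor)
#' pairs together and preserving the original row order.
#'
#' @param X,Y matrices with one observation per row (equal row counts)
#' @param fraction sampling fraction in (0, 1\]
#' @param seed integer seed or NULL
#' @return list with the subsampled `X` and `Y`
#' @export
subsampleObservations <- function(X, Y, fraction, seed = NULL) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of rows")
  n <- round(fraction * nrow(X))
  if (n < 2) stop("fraction yields fewer than 2 observations")
  idx <- .withSeed(seed, sort(sample.int(nrow(X), n)))
  list(X = X[idx, , drop = FALSE], Y = Y[idx, , drop = FALSE])
}

#' Induce dropout events in an expression matrix
#'
#' Emulates single-cell dropout on simulated (e.g. bulk-like) expression
#' profiles: per gene, entries strictly below that gene's `percentile`
#' quantile are set to 0 with probability `flipProb`, independently;
#' everything else is untouched. With the defaults (45th percentile,
#' probability 0.5) the realized dropout ratio lands near 20-25% of all
#' entries in expectation.
#'
#' @param E nonnegative expression matrix, genes x cells
#' @param percentile per-gene threshold percentile in (0, 100)
#' @param flipProb zeroing probability for sub-threshold entries
#' @param seed integer seed or NULL
#' @return the matrix with dropouts induced; attribute `"dropoutRatio"`
#'   holds the realized fraction of entries newly set to zero
#' @export
induceDropout <- function(E, percentile = 45, flipProb = 0.5, seed = NULL) {
  if (percentile <= 0 || percentile >= 100) stop("percentile must be in (0, 100)")
  if (flipProb < 0 || flipProb > 1) stop("flipProb must be in [0, 1]")
  E <- .asExpressionMatrix(E)
  out <- .withSeed(seed, {
    M <- E
    for (i in seq_len(nrow(M))) {
      thr <- stats::quantile(M[i, ], percentile / 100, names = FALSE)
      below <- which(M[i, ] < thr & M[i, ] > 0)
      if (length(below)) {
        hit <- below[stats::runif(length(below)) < flipProb]
        M[i, hit] <- 0
      }
    }
    M
  })
  attr(out, "dropoutRatio") <- mean(E > 0 & out == 0)
  out
}

#' Random Boolean threshold network generator
#'
#' Draws a network for property testing: each gene receives 1 to
#' `maxInDegree` distinct regulators, integer weights from `weightRange`,
#' random polarities, and a threshold chosen among the achievable literal
#' sums so that the rule is non-constant. Thresholds are additionally
#' rejection-sampled until every regulator is *essential* (the rule's truth
#' table depends on it): an inessential regulator leaves no trace in the
#' network's dynamics and therefore cannot be recovered from transition
#' data.
#'
#' @param N number of genes
#' @param maxInDegree maximum regulators per gene (1..N)
#' @param weightRange integer weights to draw from
#' @param seed integer seed or NULL
#' @return a [BooleanThresholdNetwork-class]
#' @export
randomBTN <- function(N, maxInDegree = 3, weightRange = 1:3, seed = NULL) {
  if (maxInDegree < 1 || maxInDegree > N)
    stop("maxInDegree must be in [1, N]")
  .withSeed(seed, {
    ruleList <- lapply(seq_len(N), function(i) {
      for (attempt in seq_len(100)) {
        k <- sample.int(maxInDegree, 1)
        regs <- sort(sample.int(N, k))
        w <- sample(weightRange, k, replace = TRUE)
        neg <- stats::runif(k) < 0.5
        ## achievable literal sums over the 2^k regulator combinations
        combos <- as.matrix(expand.grid(rep(list(0:1), k)))
        lit <- combos
        lit[, neg] <- 1 - lit[, neg, drop = FALSE]
        sums <- as.numeric(lit %*% w)
        cand <- setdiff(sort(unique(sums)), min(sums))  # non-constant range
        cand <- sample(cand)
        for (th in cand) {
          out <- as.integer(sums >= th)
          if (.allEssential(combos, out))
            return(ThresholdRule(regs, w, neg, th))
        }
      }
      stop("could not draw a non-constant rule with essential regulators")
    })
    BooleanThresholdNetwork(ruleList)
  })
}

## does the truth table depend on every input?
.allEssential <- function(combos, out) {
  k <- ncol(combos)
  for (j in seq_len(k)) {
    partner <- combos
    partner[, j] <- 1 - partner[, j]
    key <- combos %*% (2^(seq_len(k) - 1))
    pkey <- partner %*% (2^(seq_len(k) - 1))
    if (!any(out != out[match(pkey, key)])) return(FALSE)
  }
  TRUE
}
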