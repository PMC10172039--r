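## Independent brute-force oracles used to cross-check the implementation.
## These deliberately avoid the package's vectorized code paths.

## literal-by-literal evaluation of a threshold rule
oracleEvalRule <- function(rule, state) {
  total <- 0
  k <- length(rule@regulators)
  if (k > 0) {
    for (j in seq_len(k)) {
      x <- state[rule@regulators[j]]
      lit <- if (rule@negated[j]) 1 - x else x
      total <- total + rule@weights[j] * lit
    }
  }
  if (total >= rule@threshold) 1L else 0L
}

oracleSuccessor <- function(net, state) {
  unname(vapply(rules(net), oracleEvalRule, integer(1), state = state))
}

## edge-by-edge confusion tally; under the sign-aware convention a
## mis-signed edge is counted as both a false positive and a false negative
oracleConfusion <- function(W, G, signed = FALSE) {
  TP <- FP <- FN <- TN <- 0L
  for (k in seq_len(nrow(W))) for (i in seq_len(ncol(W))) {
    p <- W[k, i]; g <- G[k, i]
    if (p != 0 && g != 0) {
      if (!signed || sign(p) == g) TP <- TP + 1L
      else { FP <- FP + 1L; FN <- FN + 1L }
    }
    else if (p != 0) FP <- FP + 1L
    else if (g != 0) FN <- FN + 1L
    else TN <- TN + 1L
  }
  c(TP = TP, FP = FP, FN = FN, TN = TN)
}

## best two-cluster split of a 1-d vector by within-cluster sum of squares
oracleBestSplit <- function(x) {
  o <- order(x)
  best <- NULL; bestSS <- Inf
  for (cut in seq_len(length(x) - 1)) {
    lo <- x[o[seq_len(cut)]]; hi <- x[o[-seq_len(cut)]]
    ss <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (ss < bestSS) { bestSS <- ss; best <- x %in% hi }
  }
  as.integer(best)
}

randomRule <- function(N, maxK = 4) {
  k <- sample.int(maxK, 1)
  ThresholdRule(sort(sample.int(N, k)),
                sample(1:5, k, replace = TRUE),
                stats::runif(k) < 0.5,
                sample(-2:8, 1))
}
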