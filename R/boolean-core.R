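#' Evaluate a threshold rule on a network state
#'
#' Computes the next state of one gene: 1 iff the weighted sum of literals
#' meets the threshold. A literal is the regulator's state for an activating
#' term and its complement for an inhibiting term. Ties (sum exactly equal
#' to the threshold) fire: the comparison is `>=`, never configurable.
#'
#' @param rule a [ThresholdRule-class]
#' @param state integer/numeric vector of 0/1 gene states
#' @return 0 or 1 (integer)
#' @examples
#' r <- ThresholdRule(9L, 1, FALSE, 1)   # fires iff gene 9 is on
#' evalRule(r, c(rep(0, 8), 1))
#' @export
evalRule <- function(rule, state) {
  stopifnot(is(rule, "ThresholdRule"))
  .checkState(state)
  if (length(rule@regulators) == 0L)
    return(as.integer(0 >= rule@threshold))
  if (max(rule@regulators) > length(state))
    stop("rule references regulator index ", max(rule@regulators),
         " but state has length ", length(state))
  x <- state[rule@regulators]
  lit <- ifelse(rule@negated, 1 - x, x)
  as.integer(sum(rule@weights * lit) >= rule@threshold)
}

.checkState <- function(state) {
  if (!all(state %in% c(0, 1)))
    stop("state entries must all be 0 or 1")
  invisible(TRUE)
}

#' Synchronous update of a Boolean threshold network
#'
#' All genes evaluate their rules on the *same* input state simultaneously;
#' there are no sequential in-place effects.
#'
#' @param net a [BooleanThresholdNetwork-class]
#' @param state 0/1 vector of length `length(net)`
#' @return integer 0/1 vector: the successor state
#' @export
syncUpdate <- function(net, state) {
  stopifnot(is(net, "BooleanThresholdNetwork"))
  if (length(state) != length(net))
    stop("state length ", length(state), " != network size ", length(net))
  vapply(net@rules, evalRule, integer(1), state = state)
}

#' Simulate a synchronous trajectory
#'
#' Iterates [syncUpdate()] from an initial state. The returned matrix has
#' genes in rows and `steps + 1` time points in columns (the first column is
#' the initial state), matching the genes-by-time orientation of binarized
#' expression matrices.
#'
#' @param net a [BooleanThresholdNetwork-class]
#' @param init initial 0/1 state
#' @param steps number of update steps (>= 1)
#' @return integer matrix, `length(net)` x `(steps + 1)`, with gene row names
#' @export
simulateTrajectory <- function(net, init, steps) {
  stopifnot(is(net, "BooleanThresholdNetwork"))
  if (!is.numeric(steps) || length(steps) != 1L || steps < 1)
    stop("steps must be a single integer >= 1")
  steps <- as.integer(steps)
  .checkState(init)
  traj <- matrix(0L, nrow = length(net), ncol = steps + 1L,
                 dimnames = list(net@geneNames, NULL))
  traj[, 1L] <- as.integer(init)
  for (t in seq_len(steps))
    traj[, t + 1L] <- syncUpdate(net, traj[, t])
  traj
}

#' Enumerate all states and their synchronous successors
#'
#' Lists every one of the `2^N` global states in canonical binary-counting
#' order (gene 1 is the least-significant, fastest-varying bit) together
#' with its synchronous successor. This is the complete state-transition
#' data set used for exact network recovery.
#'
#' @param net a [BooleanThresholdNetwork-class] with at most 20 genes
#' @return list with `states` and `successors`, both `2^N` x N integer
#'   matrices (observations in rows, genes in columns)
#' @export
enumerateStatePairs <- function(net) {
  stopifnot(is(net, "BooleanThresholdNetwork"))
  n <- length(net)
  if (n > 20L)
    stop("refusing to enumerate 2^", n, " states (limit N <= 20)")
  states <- as.matrix(expand.grid(rep(list(0:1), n), KEEP.OUT.ATTRS = FALSE))
  dimnames(states) <- list(NULL, net@geneNames)
  storage.mode(states) <- "integer"
  succ <- matrix(0L, nrow = nrow(states), ncol = n,
                 dimnames = dimnames(states))
  for (i in seq_len(n)) {
    r <- net@rules[[i]]
    if (length(r@regulators) == 0L) {
      succ[, i] <- as.integer(0 >= r@threshold)
    } else {
      lit <- states[, r@regulators, drop = FALSE]
      if (any(r@negated))
        lit[, r@negated] <- 1L - lit[, r@negated, drop = FALSE]
      succ[, i] <- as.integer(lit %*% r@weights >= r@threshold)
    }
  }
  list(states = states, successors = succ)
}

#' Convert regression coefficients to a threshold rule
#'
#' The logistic log-odds `theta' x + theta0 >= 0` decision is rewritten as a
#' Boolean threshold function: a positive coefficient becomes an activating
#' term with weight `theta_k`, a negative one an inhibiting term with weight
#' `-theta_k` (the literal is complemented), zeros are dropped, and the
#' threshold is `-theta0 - sum(theta_k[theta_k < 0])`. The resulting rule
#' computes exactly the indicator of `theta' x + theta0 >= 0` on every 0/1
#' state.
#'
#' @param theta numeric vector of N regulator coefficients
#' @param theta0 intercept
#' @return a [ThresholdRule-class]
#' @export
ruleFromCoefficients <- function(theta, theta0) {
  if (any(!is.finite(theta)) || !is.finite(theta0))
    stop("coefficients must be finite")
  nz <- which(theta != 0)
  ThresholdRule(
    regulators = nz,
    weights    = abs(theta[nz]),
    negated    = theta[nz] < 0,
    threshold  = -theta0 - sum(theta[theta < 0])
  )
}

#' Render a threshold rule as text
#'
#' Produces the bracketed inequality notation, e.g.
#' `"[x5~ + 2*x6 + x9~ >= 2]"`, with inhibition marked by a trailing `~` on
#' the regulator name. The rendering is deterministic (terms in regulator
#' order) and round-trippable via [parseRule()].
#'
#' @param rule a [ThresholdRule-class]
#' @param geneNames character vector covering all regulator indices
#' @return a single string
#' @export
ruleToText <- function(rule, geneNames) {
  stopifnot(is(rule, "ThresholdRule"))
  if (length(rule@regulators) == 0L)
    return(sprintf("[0 >= %s]", .numFmt(rule@threshold)))
  if (max(rule@regulators) > length(geneNames))
    stop("geneNames does not cover all regulator indices")
  o <- order(rule@regulators)
  terms <- vapply(o, function(j) {
    nm <- geneNames[rule@regulators[j]]
    if (rule@negated[j]) nm <- paste0(nm, "~")
    w <- rule@weights[j]
    if (w == 1) nm else paste0(.numFmt(w), "*", nm)
  }, character(1))
  sprintf("[%s >= %s]", paste(terms, collapse = " + "), .numFmt(rule@threshold))
}

.numFmt <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)

#' Parse the text rendering of a threshold rule
#'
#' Inverse of [ruleToText()].
#'
#' @param text a string like `"[x5~ + 2*x6 + x9~ >= 2]"`
#' @param geneNames gene identifiers used to resolve regulator names
#' @return a [ThresholdRule-class]
#' @export
parseRule <- function(text, geneNames) {
  s <- trimws(text)
  if (!grepl("^\\[.*>=.*\\]$", s))
    stop("malformed rule text: ", text)
  s <- sub("^\\[", "", sub("\\]$", "", s))
  parts <- strsplit(s, ">=", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("malformed rule text: ", text)
  threshold <- as.numeric(trimws(parts[2]))
  lhs <- trimws(parts[1])
  if (lhs == "0")
    return(ThresholdRule(threshold = threshold))
  terms <- trimws(strsplit(lhs, "+", fixed = TRUE)[[1]])
  regs <- integer(0); wts <- numeric(0); neg <- logical(0)
  for (tm in terms) {
    if (grepl("*", tm, fixed = TRUE)) {
      wp <- strsplit(tm, "*", fixed = TRUE)[[1]]
      w <- as.numeric(trimws(wp[1])); nm <- trimws(wp[2])
    } else {
      w <- 1; nm <- tm
    }
    negated <- grepl("~$", nm)
    nm <- sub("~$", "", nm)
    idx <- match(nm, geneNames)
    if (is.na(idx)) stop("unknown gene name in rule: ", nm)
    regs <- c(regs, idx); wts <- c(wts, w); neg <- c(neg, negated)
  }
  ThresholdRule(regs, wts, neg, threshold)
}
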