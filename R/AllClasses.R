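#' @import methods
NULL

#' Boolean threshold update rule for a single gene
#'
#' A `ThresholdRule` stores one gene's update function as a linear threshold
#' unit: the gene switches on at the next time step iff
#' `sum_k w_k * l_k >= threshold`, where the literal `l_k` is the regulator's
#' state `x_k` for an activating term and its complement `1 - x_k` for an
#' inhibiting term. Weights are stored strictly positive; the activation /
#' inhibition distinction lives entirely in `negated`. A rule with no terms
#' is legal and encodes a constant gene (`1` if `0 >= threshold`, else `0`).
#'
#' @slot regulators integer vector of regulator indices (unique, >= 1)
#' @slot weights positive numeric weights, one per regulator
#' @slot negated logical, one per regulator; `TRUE` means the literal is the
#'   complemented state (inhibition)
#' @slot threshold numeric scalar; ties (`sum == threshold`) evaluate to 1
#'
#' @seealso [evalRule()], [ruleFromCoefficients()], [ruleToText()]
#' @export
setClass("ThresholdRule",
  representation(
    regulators = "integer",
    weights    = "numeric",
    negated    = "logical",
    threshold  = "numeric"
  ),
  prototype(
    regulators = integer(0),
    weights    = numeric(0),
    negated    = logical(0),
    threshold  = 0
  )
)

setValidity("ThresholdRule", function(object) {
  msg <- character(0)
  n <- length(object@regulators)
  if (length(object@weights) != n || length(object@negated) != n)
    msg <- c(msg, "regulators, weights and negated must have equal length")
  if (n > 0) {
    if (anyDuplicated(object@regulators))
      msg <- c(msg, "regulator indices must be unique within a rule")
    if (any(object@regulators < 1L))
      msg <- c(msg, "regulator indices must be >= 1")
    if (any(!is.finite(object@weights)) || any(object@weights <= 0))
      msg <- c(msg, "weights must be finite and strictly positive")
  }
  if (length(object@threshold) != 1L || !is.finite(object@threshold))
    msg <- c(msg, "threshold must be a finite scalar")
  if (length(msg)) msg else TRUE
})

#' Construct a threshold rule
#'
#' @param regulators integer indices of the regulators (may be empty)
#' @param weights strictly positive weights, one per regulator
#' @param negated logical vector; `TRUE` marks an inhibiting (complemented)
#'   literal. Recycled if scalar.
#' @param threshold the firing threshold
#' @return a [ThresholdRule-class] object
#' @examples
#' ThresholdRule(c(5L, 6L, 9L), c(1, 2, 1), c(TRUE, FALSE, TRUE), 2)
#' @export
ThresholdRule <- function(regulators = integer(0), weights = numeric(0),
                          negated = logical(0), threshold = 0) {
  if (length(negated) == 1L && length(regulators) > 1L)
    negated <- rep(negated, length(regulators))
  new("ThresholdRule",
      regulators = as.integer(regulators),
      weights    = as.numeric(weights),
      negated    = as.logical(negated),
      threshold  = as.numeric(threshold))
}

#' Boolean threshold network
#'
#' A directed gene regulatory network in which every gene carries a
#' [ThresholdRule-class] and all genes update synchronously: the state at
#' time `t + 1` is computed gene-wise from the full state at time `t`.
#'
#' @slot geneNames character vector of N gene identifiers
#' @slot rules list of N `ThresholdRule` objects; `rules[[i]]` updates gene i
#'
#' @seealso [syncUpdate()], [simulateTrajectory()], [enumerateStatePairs()]
#' @export
setClass("BooleanThresholdNetwork",
  representation(
    geneNames = "character",
    rules     = "list"
  )
)

setValidity("BooleanThresholdNetwork", function(object) {
  msg <- character(0)
  n <- length(object@geneNames)
  if (length(object@rules) != n)
    msg <- c(msg, "need exactly one rule per gene")
  if (anyDuplicated(object@geneNames))
    msg <- c(msg, "gene names must be unique")
  ok <- vapply(object@rules, is, logical(1), class2 = "ThresholdRule")
  if (!all(ok)) {
    msg <- c(msg, "all rules must be ThresholdRule objects")
  } else {
    for (r in object@rules)
      if (length(r@regulators) && max(r@regulators) > n) {
        msg <- c(msg, "rule references a regulator index beyond network size")
        break
      }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Boolean threshold network
#'
#' @param rules list of [ThresholdRule-class] objects, one per gene
#' @param geneNames gene identifiers; defaults to `x1, x2, ...`
#' @return a [BooleanThresholdNetwork-class] object
#' @export
BooleanThresholdNetwork <- function(rules, geneNames = NULL) {
  if (is.null(geneNames)) geneNames <- paste0("x", seq_along(rules))
  new("BooleanThresholdNetwork", geneNames = geneNames, rules = rules)
}

#' @describeIn BooleanThresholdNetwork-class number of genes
#' @param x a `BooleanThresholdNetwork`
#' @export
setMethod("length", "BooleanThresholdNetwork", function(x) length(x@geneNames))

#' Gene names of a network-like object
#' @param object a network object
#' @return character vector of gene identifiers
#' @export
setGeneric("geneNames", function(object) standardGeneric("geneNames"))

#' Update rules of a network-like object
#' @param object a network object
#' @return list of [ThresholdRule-class]
#' @export
setGeneric("rules", function(object) standardGeneric("rules"))

#' @rdname geneNames
#' @export
setMethod("geneNames", "BooleanThresholdNetwork", function(object) object@geneNames)

#' @rdname rules
#' @export
setMethod("rules", "BooleanThresholdNetwork", function(object) {
  names(object@rules) <- object@geneNames
  object@rules
})

setMethod("show", "BooleanThresholdNetwork", function(object) {
  cat(sprintf("BooleanThresholdNetwork with %d genes\n", length(object)))
  txt <- vapply(seq_along(object@rules), function(i)
    ruleToText(object@rules[[i]], object@geneNames), character(1))
  for (i in seq_along(txt))
    cat(sprintf("  %s : %s\n", object@geneNames[i], txt[i]))
})

#' Inferred signed regulatory network
#'
#' The result of [inferNetwork()]: an N x N signed weight matrix (entry
#' `[k, i]` is the normalized influence of regulator k on target i, in
#' `[-1, 1]` with per-target L-infinity normalization), the executable
#' [BooleanThresholdNetwork-class] assembled from the unnormalized pruned
#' coefficients, a per-gene fit report, and run metadata (seed, tuning
#' parameters) sufficient to reproduce the run.
#'
#' @slot weights N x N numeric matrix, regulators in rows, targets in columns
#' @slot network the executable threshold network
#' @slot fits per-gene fit report (list)
#' @slot metadata run provenance (list)
#' @export
setClass("InferredNetwork",
  representation(
    weights  = "matrix",
    network  = "BooleanThresholdNetwork",
    fits     = "list",
    metadata = "list"
  )
)

setValidity("InferredNetwork", function(object) {
  msg <- character(0)
  w <- object@weights
  n <- length(object@network@geneNames)
  if (!all(dim(w) == c(n, n)))
    msg <- c(msg, "weights must be N x N for the N genes of the network")
  if (any(abs(w) > 1 + 1e-12))
    msg <- c(msg, "normalized weights must lie in [-1, 1]")
  nz <- apply(w, 2, function(col) if (any(col != 0)) max(abs(col)) else 1)
  if (any(abs(nz - 1) > 1e-8))
    msg <- c(msg, "each nonzero column must have maximum |weight| equal to 1")
  if (length(msg)) msg else TRUE
})

#' @rdname geneNames
#' @export
setMethod("geneNames", "InferredNetwork", function(object) object@network@geneNames)

#' @rdname rules
#' @export
setMethod("rules", "InferredNetwork", function(object) rules(object@network))

#' Signed weight matrix of an inferred network
#' @param object an [InferredNetwork-class]
#' @return N x N numeric matrix (regulator rows, target columns)
#' @export
setGeneric("weightMatrix", function(object) standardGeneric("weightMatrix"))

#' @rdname weightMatrix
#' @export
setMethod("weightMatrix", "InferredNetwork", function(object) object@weights)

#' Executable rule network of an inferred network
#' @param object an [InferredNetwork-class]
#' @return a [BooleanThresholdNetwork-class]
#' @export
setGeneric("ruleNetwork", function(object) standardGeneric("ruleNetwork"))

#' @rdname ruleNetwork
#' @export
setMethod("ruleNetwork", "InferredNetwork", function(object) object@network)

setMethod("show", "InferredNetwork", function(object) {
  n <- length(object@network@geneNames)
  ne <- sum(object@weights != 0)
  np <- sum(object@weights > 0)
  cat(sprintf("InferredNetwork: %d genes, %d signed edges (%d activating, %d inhibiting)\n",
              n, ne, np, ne - np))
  if (!is.null(object@metadata$seed))
    cat(sprintf("  seed: %s\n", object@metadata$seed))
  cat("  access: weightMatrix(), ruleNetwork(), geneNames()\n")
})

#' Evaluation of an inferred network against a gold standard
#'
#' Confusion counts over the N^2 ordered candidate edges (self-loops
#' included) plus the derived structural metrics, the two-point AUROC and
#' AUPR, and (optionally) the one-step dynamical accuracy.
#'
#' @slot counts named integer vector `TP`, `FP`, `FN`, `TN`
#' @slot stAcc,recall,precision,fpr,fmeasure,auroc,aupr numeric scalars in \[0, 1\]
#' @slot dyAcc dynamical accuracy, `NA` unless state predictions were supplied
#' @slot signMode `"SIGN0"` (presence/absence) or `"SIGN1"` (sign-aware)
#' @export
setClass("EvaluationReport",
  representation(
    counts    = "integer",
    stAcc     = "numeric",
    recall    = "numeric",
    precision = "numeric",
    fpr       = "numeric",
    fmeasure  = "numeric",
    auroc     = "numeric",
    aupr      = "numeric",
    dyAcc     = "numeric",
    signMode  = "character"
  )
)

setMethod("show", "EvaluationReport", function(object) {
  c_ <- object@counts
  cat(sprintf("EvaluationReport (%s): TP=%d FP=%d FN=%d TN=%d\n",
              object@signMode, c_["TP"], c_["FP"], c_["FN"], c_["TN"]))
  cat(sprintf("  StAcc=%.3f Recall=%.3f Precision=%.3f FPR=%.3f F=%.3f\n",
              object@stAcc, object@recall, object@precision, object@fpr,
              object@fmeasure))
  cat(sprintf("  AUROC=%.3f AUPR=%.3f DyAcc=%s\n", object@auroc, object@aupr,
              ifelse(is.na(object@dyAcc), "NA", sprintf("%.3f", object@dyAcc))))
})

#' Flatten an evaluation report to a named numeric vector
#'
#' @param x an [EvaluationReport-class]
#' @return named numeric vector of all metrics and counts
#' @export
reportMetrics <- function(x) {
  stopifnot(is(x, "EvaluationReport"))
  c(StAcc = x@stAcc, Recall = x@recall, Precision = x@precision,
    FPR = x@fpr, Fmeasure = x@fmeasure, AUROC = x@auroc, AUPR = x@aupr,
    DyAcc = x@dyAcc, TP = unname(x@counts["TP"]), FP = unname(x@counts["FP"]),
    FN = unname(x@counts["FN"]), TN = unname(x@counts["TN"]))
}

#' @rdname reportMetrics
#' @param ... ignored
#' @export
as.numeric.EvaluationReport <- function(x, ...) reportMetrics(x)
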