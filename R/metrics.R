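#' Confusion counts over the candidate-edge universe
#'
#' Tallies predicted against gold-standard edges over all N^2 ordered gene
#' pairs, self-loops included. In `SIGN0` mode an edge is simply a nonzero
#' entry on either side and a true positive needs both nonzero. In `SIGN1`
#' mode a true positive additionally requires matching sign; a nonzero
#' prediction with the wrong sign on a gold edge counts as one false
#' positive *and* leaves the gold edge as a false negative. Both-zero pairs
#' are true negatives. Note that under `SIGN1` a mis-signed edge therefore
#' appears in two counts and the four counts can sum to more than N^2;
#' [structuralMetrics()] takes the universe size explicitly for this reason.
#'
#' @param predWeights N x N signed numeric matrix (regulator rows, target
#'   columns)
#' @param gold N x N matrix with entries in `{-1, 0, +1}`
#' @param signMode `"SIGN0"` or `"SIGN1"`
#' @return named integer vector `TP`, `FP`, `FN`, `TN` (sums to N^2)
#' @export
edgeConfusion <- function(predWeights, gold, signMode = c("SIGN0", "SIGN1")) {
  signMode <- match.arg(signMode)
  predWeights <- as.matrix(predWeights); gold <- as.matrix(gold)
  if (!all(dim(predWeights) == dim(gold)))
    stop("prediction and gold standard must have the same shape")
  if (!all(gold %in% c(-1, 0, 1)))
    stop("gold entries must be in {-1, 0, +1}")
  pe <- predWeights != 0
  ge <- gold != 0
  if (signMode == "SIGN0") {
    TP <- sum(pe & ge)
  } else {
    TP <- sum(pe & ge & (sign(predWeights) == gold))
  }
  FP <- sum(pe) - TP
  FN <- sum(ge) - TP
  TN <- sum(!pe & !ge)
  c(TP = as.integer(TP), FP = as.integer(FP),
    FN = as.integer(FN), TN = as.integer(TN))
}

#' Structural metrics from confusion counts
#'
#' `StAcc = (TP + TN) / N^2` (the denominator is the full ordered-pair
#' universe including self-loops), `Recall = TP / (TP + FN)`,
#' `Precision = TP / (TP + FP)`, `FPR = FP / (FP + TN)`, and the F-measure
#' `2PR / (P + R)`. Zero-denominator conventions: precision is 1 when
#' neither predictions nor gold edges exist, 0 when predictions are empty
#' but gold edges exist; recall is 1 for an empty gold standard; F is 0
#' when `P + R = 0`.
#'
#' @param counts named vector from [edgeConfusion()]
#' @param universe number of candidate pairs (N^2); defaults to the sum of
#'   the counts, which is exact except for sign-aware counts containing
#'   mis-signed edges
#' @return named numeric vector `StAcc`, `Recall`, `Precision`, `FPR`,
#'   `Fmeasure`
#' @export
structuralMetrics <- function(counts, universe = NULL) {
  TP <- counts[["TP"]]; FP <- counts[["FP"]]
  FN <- counts[["FN"]]; TN <- counts[["TN"]]
  total <- if (is.null(universe)) TP + FP + FN + TN else universe
  recall <- if (TP + FN == 0) 1 else TP / (TP + FN)
  precision <- if (TP + FP == 0) { if (TP + FN == 0) 1 else 0 } else TP / (TP + FP)
  fpr <- if (FP + TN == 0) 0 else FP / (FP + TN)
  f <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  c(StAcc = (TP + TN) / total, Recall = recall, Precision = precision,
    FPR = fpr, Fmeasure = f)
}

#' Two-point AUROC of a hard edge classifier
#'
#' A binary (unranked) edge prediction gives a single ROC operating point
#' `(FPR, TPR)`; the area under the two-segment ROC through it is
#' `(TPR + 1 - FPR) / 2`. Chance-level predictions (`TPR == FPR`) score
#' 0.5 and a perfect prediction scores 1.
#'
#' @param counts named vector from [edgeConfusion()]
#' @return AUROC in \[0, 1\]
#' @export
aurocBinary <- function(counts) {
  m <- structuralMetrics(counts)
  unname((m["Recall"] + 1 - m["FPR"]) / 2)
}

#' Area under the precision-recall curve
#'
#' `mode = "binary_counts"` treats the prediction as a hard classifier and
#' integrates the three-point PR curve `(0, 1) -> (R, P) -> (1, prevalence)`
#' with linear interpolation, where prevalence is the gold edge density.
#' `mode = "ranked"` ranks candidate edges by decreasing `|weight|` and
#' accumulates standard average precision (precision at each recall
#' increment), for comparison with score-based methods.
#'
#' @param predWeights N x N signed weight matrix
#' @param gold N x N gold matrix in `{-1, 0, +1}`
#' @param mode `"binary_counts"` or `"ranked"`
#' @param signMode passed to [edgeConfusion()] for the binary mode
#' @return AUPR in \[0, 1\]
#' @export
auprScore <- function(predWeights, gold, mode = c("binary_counts", "ranked"),
                      signMode = "SIGN0") {
  mode <- match.arg(mode)
  gold <- as.matrix(gold)
  prevalence <- sum(gold != 0) / length(gold)
  if (mode == "binary_counts") {
    counts <- edgeConfusion(predWeights, gold, signMode)
    m <- structuralMetrics(counts)
    R <- m[["Recall"]]; P <- m[["Precision"]]
    if (counts[["TP"]] + counts[["FP"]] == 0) return(prevalence)
    ## trapezoids (0,1)-(R,P) and (R,P)-(1,prevalence)
    return(R * (1 + P) / 2 + (1 - R) * (P + prevalence) / 2)
  }
  score <- abs(as.matrix(predWeights))
  truth <- as.integer(gold != 0)
  if (sum(truth) == 0) return(1)
  o <- order(-score, seq_along(score))  # stable: ties by index
  truth <- truth[o]
  tp <- cumsum(truth)
  prec <- tp / seq_along(truth)
  sum(prec[truth == 1]) / sum(truth)
}

#' One-step dynamical accuracy
#'
#' Fraction of gene states correctly predicted one step ahead: predicted
#' states for times `2..T` are compared bit-wise against the observed
#' binarized matrix.
#'
#' @param predicted genes x (T-1) 0/1 matrix from [predictStates()]
#' @param observed genes x T observed 0/1 matrix
#' @return accuracy in \[0, 1\]
#' @export
dynamicAccuracy <- function(predicted, observed) {
  predicted <- as.matrix(predicted); observed <- as.matrix(observed)
  if (nrow(predicted) != nrow(observed) ||
      ncol(predicted) != ncol(observed) - 1L)
    stop("shape mismatch: predicted must be genes x (T-1) for observed genes x T")
  target <- observed[, -1L, drop = FALSE]
  mean(predicted == target)
}

#' Evaluate an inferred network against a gold standard
#'
#' Bundles [edgeConfusion()], [structuralMetrics()], [aurocBinary()] and
#' [auprScore()] into an [EvaluationReport-class]; when the observed binary
#' matrix is supplied, the one-step dynamical accuracy of the inferred
#' rules is included.
#'
#' @param net an [InferredNetwork-class] or a signed weight matrix
#' @param gold N x N gold matrix in `{-1, 0, +1}`
#' @param signMode `"SIGN0"` or `"SIGN1"`
#' @param observed optional genes x T observed 0/1 matrix for DyAcc
#' @return an [EvaluationReport-class]
#' @export
evaluateNetwork <- function(net, gold, signMode = c("SIGN0", "SIGN1"),
                            observed = NULL) {
  signMode <- match.arg(signMode)
  W <- if (is(net, "InferredNetwork")) weightMatrix(net) else as.matrix(net)
  counts <- edgeConfusion(W, gold, signMode)
  m <- structuralMetrics(counts, universe = length(gold))
  dy <- NA_real_
  if (!is.null(observed)) {
    if (!is(net, "InferredNetwork"))
      stop("observed states require an InferredNetwork with rules")
    dy <- dynamicAccuracy(predictStates(net, observed), observed)
  }
  new("EvaluationReport", counts = counts,
      stAcc = unname(m["StAcc"]), recall = unname(m["Recall"]),
      precision = unname(m["Precision"]), fpr = unname(m["FPR"]),
      fmeasure = unname(m["Fmeasure"]),
      auroc = aurocBinary(counts),
      aupr = auprScore(W, gold, "binary_counts", signMode),
      dyAcc = dy, signMode = signMode)
}
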