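#' Result of a single penalized logistic fit
#'
#' @slot theta N regulator coefficients (original 0/1 scale)
#' @slot theta0 intercept; `+Inf`/`-Inf` sentinel for a degenerate
#'   (constant-response) target
#' @slot lambda,alpha the penalty actually applied
#' @slot degenerate TRUE when the response was constant and no regression
#'   was fitted
#' @export
setClass("FitResult",
  representation(
    theta      = "numeric",
    theta0     = "numeric",
    lambda     = "numeric",
    alpha      = "numeric",
    degenerate = "logical"
  )
)

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: %d coefficients (%d nonzero), lambda=%g, alpha=%g%s\n",
              length(object@theta), sum(object@theta != 0), object@lambda,
              object@alpha, if (object@degenerate) " [degenerate]" else ""))
})

#' Elastic-net logistic regression for one target gene
#'
#' Minimizes the negative Bernoulli log-likelihood plus the elastic-net
#' penalty `lambda * (alpha * ||theta||_1 + (1 - alpha) * ||theta||_2^2)`
#' over the regulator coefficients; the intercept is never penalized.
#' Fitting goes through [glmnet::glmnet()] with `standardize = FALSE`, so
#' coefficients stay on the original 0/1 state scale.
#'
#' `lambda = 0` requests an unpenalized fit. Complete transition data from
#' a realizable Boolean rule is perfectly separable, where the unpenalized
#' maximum-likelihood optimum diverges, so a tiny ridge (`ridgeFloor`,
#' default 1e-8) is silently substituted: the coefficient vector then
#' follows the max-margin direction, which preserves both the sign pattern
#' and the classification of every observation.
#'
#' A constant response cannot be regressed; the fit is flagged degenerate
#' with zero coefficients and a `+/-Inf` intercept sentinel, which
#' [inferNetwork()] maps to a constant rule.
#'
#' @param X design matrix (observations x regulators); a trailing all-ones
#'   intercept column, as produced by [buildDesign()], is detected and
#'   handled internally
#' @param y 0/1 response vector
#' @param lambda penalty strength (>= 0); 0 means unpenalized (ridge floor)
#' @param alpha elastic-net mixing in \[0, 1\] (1 = lasso, 0 = ridge)
#' @param maxIter iteration cap passed to glmnet
#' @param ridgeFloor ridge substitute for `lambda = 0`
#' @return a [FitResult-class]
#' @export
fitLogisticElasticNet <- function(X, y, lambda = 0, alpha = 1,
                                  maxIter = 1e5, ridgeFloor = 1e-8) {
  X <- .stripIntercept(as.matrix(X))
  y <- as.numeric(y)
  if (nrow(X) < 2L) stop("need at least 2 observations")
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (!all(y %in% c(0, 1))) stop("y must be 0/1")
  if (length(unique(y)) < 2L) {
    return(new("FitResult", theta = numeric(ncol(X)),
               theta0 = if (y[1] == 1) Inf else -Inf,
               lambda = lambda, alpha = alpha, degenerate = TRUE))
  }
  if (lambda == 0) {
    path <- c(10, 1, 0.1, 0.01, 1e-4, ridgeFloor)
    fit <- .quietSmallClass(
      glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                     lambda = path, standardize = FALSE,
                     thresh = 1e-12, maxit = maxIter))
  } else {
    path <- sort(unique(c(lambda * 100, lambda * 10, lambda)), decreasing = TRUE)
    fit <- .quietSmallClass(
      glmnet::glmnet(X, y, family = "binomial", alpha = alpha,
                     lambda = path, standardize = FALSE,
                     thresh = 1e-12, maxit = maxIter))
  }
  k <- length(fit$lambda)
  new("FitResult", theta = as.numeric(fit$beta[, k]),
      theta0 = unname(fit$a0[k]), lambda = lambda, alpha = alpha,
      degenerate = FALSE)
}

#' Cross-validated selection of the elastic-net penalty
#'
#' For each mixing value in `alphaGrid`, a 100-value log-spaced lambda path
#' is cross-validated on binomial deviance with folds stratified by the
#' response (so both classes appear in every fold whenever possible); the
#' `(alpha, lambda)` pair with the smallest mean CV deviance wins. With the
#' same seed and data the selection is deterministic.
#'
#' @param X design matrix (intercept column tolerated)
#' @param y 0/1 response
#' @param alphaGrid candidate mixing values
#' @param nFolds number of CV folds (reduced to leave-one-out with a
#'   message when there are fewer observations than folds)
#' @param seed integer seed for the fold assignment, or NULL
#' @return list with `lambda`, `alpha`, and a per-alpha summary data frame
#' @export
selectHyperparameters <- function(X, y, alphaGrid = seq(0, 1, by = 0.1),
                                  nFolds = 10, seed = NULL) {
  X <- .stripIntercept(as.matrix(X))
  y <- as.numeric(y)
  n <- length(y)
  if (n < 2L || nFolds < 2L) stop("need at least 2 observations and 2 folds")
  if (n < nFolds) {
    message("fewer observations than folds; falling back to leave-one-out")
    nFolds <- n
  }
  foldid <- .stratifiedFolds(y, nFolds, seed)
  best <- NULL
  summ <- data.frame(alpha = alphaGrid, lambda = NA_real_, cvm = NA_real_)
  for (j in seq_along(alphaGrid)) {
    cv <- .quietSmallClass(
      glmnet::cv.glmnet(X, y, family = "binomial", alpha = alphaGrid[j],
                        foldid = foldid, nlambda = 100,
                        type.measure = "deviance", standardize = FALSE))
    i <- which.min(cv$cvm)
    summ$lambda[j] <- cv$lambda[i]
    summ$cvm[j] <- cv$cvm[i]
    if (is.null(best) || cv$cvm[i] < best$cvm)
      best <- list(lambda = cv$lambda[i], alpha = alphaGrid[j], cvm = cv$cvm[i])
  }
  list(lambda = best$lambda, alpha = best$alpha, summary = summ)
}

.stratifiedFolds <- function(y, nFolds, seed = NULL) {
  .withSeed(seed, {
    foldid <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      foldid[idx] <- rep_len(seq_len(nFolds), length(idx))
    }
    foldid
  })
}

.withSeed <- function(seed, expr) {
  if (is.null(seed)) expr
  else withr::with_seed(as.integer(seed), expr)
}

## silence glmnet's small-class-size chatter (expected with short series);
## genuine non-convergence warnings still propagate
.quietSmallClass <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("fewer than 8 observations", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

#' Perturb a binary design matrix
#'
#' Adds i.i.d. Gaussian noise `N(0, sigma^2)` to every entry of the design.
#' A tiny perturbation breaks exact duplicate columns (the multi-collinearity
#' typical of binarized expression data) and makes the design full column
#' rank with probability 1, while leaving fitted effects essentially
#' unchanged. A trailing all-ones intercept column is left untouched.
#'
#' @param X design matrix
#' @param sigma perturbation standard deviation (> 0, "sufficiently small";
#'   values below 0.1 are sensible for 0/1 designs)
#' @param seed integer seed or NULL
#' @return perturbed matrix of the same shape
#' @export
perturbDesign <- function(X, sigma = 1e-4, seed = NULL) {
  if (sigma <= 0) stop("sigma must be > 0")
  X <- as.matrix(X)
  hasInt <- ncol(X) >= 2L && all(X[, ncol(X)] == 1)
  .withSeed(seed, {
    noise <- matrix(stats::rnorm(length(X), 0, sigma), nrow(X), ncol(X))
    if (hasInt) noise[, ncol(X)] <- 0
    X + noise
  })
}

#' Zero out sub-threshold coefficients
#'
#' Sets `theta_k` to 0 wherever `|theta_k| < sigma` (strictly less than:
#' a coefficient exactly at the cutoff is kept). Used to remove the
#' spurious effects introduced by design perturbation.
#'
#' @param theta coefficient vector
#' @param sigma cutoff (> 0)
#' @return pruned coefficient vector
#' @export
pruneCoefficients <- function(theta, sigma) {
  if (sigma <= 0) stop("sigma must be > 0")
  theta[abs(theta) < sigma] <- 0
  theta
}

#' L-infinity normalization of regulator coefficients
#'
#' Divides a target gene's coefficient vector by its maximum absolute
#' entry, so the strongest regulator gets weight +/-1 and all weights lie
#' in `[-1, 1]`. A zero vector is returned unchanged. The intercept is not
#' part of the vector and never enters the norm.
#'
#' @param theta coefficient vector over the N regulators
#' @return normalized vector
#' @export
normalizeLinf <- function(theta) {
  m <- max(abs(theta))
  if (m > 0) theta / m else theta
}

#' Significance-based regulator screening
#'
#' Drop-one likelihood-ratio screening of candidate regulators: for each
#' regulator k, the unpenalized logistic model is refitted without column
#' k, and the deviance increase is compared against a chi-squared(1)
#' quantile at a Bonferroni-corrected level (`level / nTests`, with
#' `nTests` defaulting to the N^2 ordered candidate edges of an N-gene
#' network). Regulators whose removal does not significantly worsen the
#' fit are screened out. On perfectly separable data every essential
#' regulator's removal breaks separation, so true regulators always
#' survive; under noise, weakly supported edges are dropped, which keeps
#' the called edge set conservative (high precision).
#'
#' @param X design matrix (intercept column tolerated)
#' @param y 0/1 response
#' @param level familywise significance level (default 1e-4)
#' @param nTests Bonferroni divisor; defaults to `ncol(X)^2`
#' @return list with logical `keep`, the per-regulator deviance drops
#'   (`lrt`), and the `cutoff` used
#' @export
screenRegulators <- function(X, y, level = 1e-4, nTests = NULL) {
  X <- .stripIntercept(as.matrix(X))
  y <- as.numeric(y)
  p <- ncol(X)
  if (is.null(nTests)) nTests <- p^2
  cutoff <- stats::qchisq(1 - level / nTests, df = 1)
  if (length(unique(y)) < 2L)
    return(list(keep = rep(FALSE, p), lrt = rep(0, p), cutoff = cutoff))
  dev <- function(M) suppressWarnings(
    stats::glm.fit(cbind(1, M), y, family = stats::binomial())$deviance)
  full <- dev(X)
  lrt <- vapply(seq_len(p), function(k)
    dev(X[, -k, drop = FALSE]) - full, numeric(1))
  list(keep = lrt > cutoff, lrt = lrt, cutoff = cutoff)
}

#' Infer a signed Boolean threshold network from a binary matrix
#'
#' The full inference pipeline, run independently for every target gene:
#'
#' 1. build the design pairs (states at times `1..T-1` as predictors, the
#'    target's state at times `2..T` as response);
#' 2. optionally perturb the shared design once (`perturb = TRUE`) to break
#'    collinearity between duplicated gene profiles;
#' 3. fix the penalty (`lambda`, `alpha`) or select it by cross-validation
#'    (`cv = TRUE`);
#' 4. fit the elastic-net logistic regression;
#' 5. call edges: significance screening (drop-one likelihood-ratio test at
#'    a Bonferroni-corrected familywise `screenLevel`, enabled by default)
#'    followed by the sigma cutoff on raw and on L-infinity-normalized
#'    coefficients;
#' 6. convert surviving coefficients to an executable threshold rule and a
#'    normalized signed weight column.
#'
#' A constant target yields a constant rule and an all-zero weight column.
#' Failures in one gene's fit do not abort the others; failed genes are
#' listed in the fit report.
#'
#' @param B integer 0/1 matrix, genes x time points (pseudo-time ordered)
#' @param lambda,alpha fixed penalty used when `cv = FALSE`
#' @param cv select `(lambda, alpha)` per gene by [selectHyperparameters()]
#' @param alphaGrid,nFolds CV policy
#' @param perturb add the Gaussian design perturbation
#' @param sigma perturbation SD and pruning cutoff (one value for both)
#' @param screen enable significance-based edge calling
#' @param screenLevel familywise level of the screen
#' @param ridgeFloor see [fitLogisticElasticNet()]
#' @param pruneAfterNormalize apply the sigma cutoff only on the normalized
#'   scale (sensitivity option; default prunes raw coefficients first)
#' @param seed integer seed driving perturbation and CV fold draws
#' @param observedSuccessors optional 0/1 matrix of the same shape as `B`
#'   whose column j is the observed successor of state column j; when given,
#'   every column of `B` is an independent (state, successor) observation
#'   instead of a consecutive time series
#' @return an [InferredNetwork-class]
#' @examples
#' bench <- generateBenchmark(delta = 0)
#' net <- inferNetwork(t(bench$X), observedSuccessors = t(bench$Y))
#' sum(weightMatrix(net) != 0)  # 25 edges
#' @export
inferNetwork <- function(B, lambda = 0, alpha = 1, cv = FALSE,
                         alphaGrid = seq(0, 1, by = 0.1), nFolds = 10,
                         perturb = FALSE, sigma = 1e-4,
                         screen = TRUE, screenLevel = 1e-4,
                         ridgeFloor = 1e-8, pruneAfterNormalize = FALSE,
                         seed = NULL, observedSuccessors = NULL) {
  B <- as.matrix(B)
  if (!all(B %in% c(0L, 1L))) stop("B must be a 0/1 matrix")
  N <- nrow(B)
  genes <- rownames(B)
  if (is.null(genes)) genes <- paste0("x", seq_len(N))

  if (is.null(observedSuccessors)) {
    d1 <- buildDesign(B, 1L)
    X <- d1$X[, seq_len(N), drop = FALSE]
    Y <- t(B[, -1L, drop = FALSE])
  } else {
    ## explicit (state, successor) pairs, e.g. exhaustive enumeration data:
    ## column j of observedSuccessors is the successor of column j of B
    observedSuccessors <- as.matrix(observedSuccessors)
    if (!all(dim(observedSuccessors) == dim(B)))
      stop("observedSuccessors must have the same shape as B")
    X <- t(B)
    Y <- t(observedSuccessors)
  }
  storage.mode(X) <- "double"

  Xfit <- if (perturb) perturbDesign(X, sigma, seed = .deriveSeed(seed, 1L)) else X

  W <- matrix(0, N, N, dimnames = list(genes, genes))
  ruleList <- vector("list", N)
  fits <- vector("list", N)
  for (i in seq_len(N)) {
    y <- as.integer(Y[, i])
    res <- tryCatch(
      .inferGene(Xfit, y, lambda, alpha, cv, alphaGrid, nFolds, sigma,
                 screen, screenLevel, ridgeFloor, pruneAfterNormalize,
                 seed = .deriveSeed(seed, 1L + i)),
      error = function(e) list(error = conditionMessage(e)))
    if (!is.null(res$error)) {
      ruleList[[i]] <- ThresholdRule(threshold = 1)  # constant 0
      fits[[i]] <- list(gene = genes[i], error = res$error)
      next
    }
    W[, i] <- res$weights
    ruleList[[i]] <- res$rule
    fits[[i]] <- c(list(gene = genes[i]), res$report)
  }
  names(fits) <- genes

  failed <- genes[vapply(fits, function(f) !is.null(f$error), logical(1))]
  new("InferredNetwork",
      weights = W,
      network = BooleanThresholdNetwork(ruleList, genes),
      fits = fits,
      metadata = list(seed = seed, sigma = sigma, lambda = lambda,
                      alpha = alpha, cv = cv, perturb = perturb,
                      screen = screen, screenLevel = screenLevel,
                      ridgeFloor = ridgeFloor,
                      pruneAfterNormalize = pruneAfterNormalize,
                      failedGenes = failed,
                      package = as.character(utils::packageVersion("btnet"))))
}

.inferGene <- function(X, y, lambda, alpha, cv, alphaGrid, nFolds, sigma,
                       screen, screenLevel, ridgeFloor, pruneAfterNormalize,
                       seed) {
  N <- ncol(X)
  if (length(unique(y)) < 2L) {
    rule <- if (y[1] == 1L) ThresholdRule(threshold = 0)
            else ThresholdRule(threshold = 1)
    return(list(weights = numeric(N), rule = rule,
                report = list(degenerate = TRUE, lambda = NA, alpha = NA,
                              nEdges = 0L)))
  }
  if (cv) {
    hp <- selectHyperparameters(X, y, alphaGrid, nFolds, seed = seed)
    lambda <- hp$lambda; alpha <- hp$alpha
  }
  fit <- fitLogisticElasticNet(X, y, lambda = lambda, alpha = alpha,
                               ridgeFloor = ridgeFloor)
  theta <- fit@theta
  if (screen) {
    sc <- screenRegulators(X, y, level = screenLevel, nTests = N^2)
    theta[!sc$keep] <- 0
  }
  if (pruneAfterNormalize) {
    tn <- normalizeLinf(theta)
    theta[abs(tn) < sigma] <- 0
  } else {
    theta <- pruneCoefficients(theta, sigma)
    theta[abs(normalizeLinf(theta)) < sigma] <- 0
  }
  list(weights = normalizeLinf(theta),
       rule = ruleFromCoefficients(theta, fit@theta0),
       report = list(degenerate = FALSE, lambda = lambda, alpha = alpha,
                     nEdges = sum(theta != 0)))
}

.deriveSeed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) %% 1000000L) * 1009L + as.integer(k)
}

#' One-step-ahead state prediction (teacher forcing)
#'
#' Applies the inferred rules to each *observed* state column `t` of the
#' binarized matrix to predict the states at `t + 1`, for `t = 1..T-1`.
#' Predictions never feed back into later predictions.
#'
#' @param net an [InferredNetwork-class] or [BooleanThresholdNetwork-class]
#' @param B observed 0/1 matrix, genes x time points, gene order matching
#'   the network (checked by name when both carry names)
#' @return integer 0/1 matrix, genes x (T-1)
#' @export
predictStates <- function(net, B) {
  if (is(net, "InferredNetwork")) net <- net@network
  stopifnot(is(net, "BooleanThresholdNetwork"))
  B <- as.matrix(B)
  if (nrow(B) != length(net))
    stop("gene mismatch: network has ", length(net), " genes, B has ", nrow(B))
  if (!is.null(rownames(B)) && !identical(rownames(B), net@geneNames))
    stop("gene names of B do not match the network")
  T_ <- ncol(B)
  pred <- matrix(0L, nrow(B), T_ - 1L,
                 dimnames = list(net@geneNames, NULL))
  for (t in seq_len(T_ - 1L))
    pred[, t] <- syncUpdate(net, B[, t])
  pred
}
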