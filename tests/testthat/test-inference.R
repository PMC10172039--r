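test_that("unpenalized fits separate realizable targets perfectly", {
  set.seed(17)
  X <- matrix(sample(0:1, 200 * 5, replace = TRUE), ncol = 5)
  y <- X[, 3]  # target copies regulator 3
  fit <- fitLogisticElasticNet(X, y, lambda = 0)
  scores <- as.numeric(X %*% fit@theta + fit@theta0)
  expect_identical(as.integer(scores >= 0), as.integer(y))
  # the aggregated rule computes the identity on gene 3
  rule <- ruleFromCoefficients(pruneCoefficients(fit@theta, 1e-4), fit@theta0)
  got <- vapply(seq_len(nrow(X)), function(j) evalRule(rule, X[j, ]), integer(1))
  expect_identical(got, as.integer(y))
})

test_that("a dominating lasso penalty shrinks all coefficients to zero", {
  set.seed(18)
  X <- matrix(sample(0:1, 100 * 4, replace = TRUE), ncol = 4)
  y <- X[, 1]
  fit <- fitLogisticElasticNet(X, y, lambda = 50, alpha = 1)
  expect_identical(unname(fit@theta), rep(0, 4))
  # intercept falls back to the log-odds of the response mean
  expect_equal(fit@theta0, stats::qlogis(mean(y)), tolerance = 0.05)
})

test_that("constant responses yield a flagged degenerate fit", {
  X <- matrix(sample(0:1, 40, replace = TRUE), ncol = 4)
  fit1 <- fitLogisticElasticNet(X, rep(1, 10), lambda = 0)
  expect_true(fit1@degenerate)
  expect_identical(fit1@theta0, Inf)
  fit0 <- fitLogisticElasticNet(X, rep(0, 10), lambda = 0)
  expect_identical(fit0@theta0, -Inf)
  expect_true(all(fit0@theta == 0))
})

test_that("cross-validation selects heavy shrinkage for noise and light for signal", {
  set.seed(31)
  nTop <- 0L; nBottom <- 0L
  for (s in 1:8) {
    X <- matrix(sample(0:1, 60 * 4, replace = TRUE), ncol = 4)
    yNoise <- sample(0:1, 60, replace = TRUE)          # independent of X
    ySignal <- as.integer(X[, 1] + X[, 2] >= 1)        # realizable rule
    hpN <- selectHyperparameters(X, yNoise, alphaGrid = 1, nFolds = 5, seed = s)
    hpS <- selectHyperparameters(X, ySignal, alphaGrid = 1, nFolds = 5, seed = s)
    # rank the selected lambda on its own 100-value path
    path <- glmnet::glmnet(X, yNoise, family = "binomial", alpha = 1,
                           nlambda = 100, standardize = FALSE)$lambda
    if (hpN$lambda >= stats::quantile(path, 0.75)) nTop <- nTop + 1L
    pathS <- glmnet::glmnet(X, ySignal, family = "binomial", alpha = 1,
                            nlambda = 100, standardize = FALSE)$lambda
    if (hpS$lambda <= stats::median(pathS)) nBottom <- nBottom + 1L
  }
  expect_gte(nTop, 6L)     # noise: lambda near the top of the path
  expect_gte(nBottom, 6L)  # signal: little shrinkage needed

  # determinism: same seed, same data -> identical selection
  X <- matrix(sample(0:1, 60 * 4, replace = TRUE), ncol = 4)
  y <- as.integer(X[, 1] | X[, 3])
  a <- selectHyperparameters(X, y, alphaGrid = c(0.5, 1), nFolds = 5, seed = 99)
  b <- selectHyperparameters(X, y, alphaGrid = c(0.5, 1), nFolds = 5, seed = 99)
  expect_identical(a[c("lambda", "alpha")], b[c("lambda", "alpha")])
})

test_that("design perturbation is seeded, bounded and repairs rank", {
  X <- cbind(a = c(1, 0, 1, 1, 0), b = c(1, 0, 1, 1, 0), c = c(0, 1, 1, 0, 0))
  expect_lt(qr(X)$rank, 3)  # duplicated column

  p1 <- perturbDesign(X, sigma = 1e-4, seed = 1)
  p2 <- perturbDesign(X, sigma = 1e-4, seed = 1)
  expect_identical(p1, p2)                                 # seeded determinism
  expect_identical(qr(p1)$rank, 3L)                        # full column rank
  expect_true(all(abs(p1 - X) < 6e-4))                     # within 6 sigma

  # the intercept column is sacred
  Xi <- cbind(X, `(Intercept)` = 1)
  pi_ <- perturbDesign(Xi, sigma = 1e-4, seed = 2)
  expect_identical(unname(pi_[, 4]), rep(1, 5))
  expect_error(perturbDesign(X, sigma = 0), "sigma")
})

test_that("coefficient pruning is strict and boundary-keeping", {
  expect_identical(pruneCoefficients(c(0.5, 1e-6, -0.3), 1e-4),
                   c(0.5, 0, -0.3))
  th <- c(0.5, -0.2, 0.1)
  expect_identical(pruneCoefficients(th, 1e-4), th)   # all above: identity
  # |theta| exactly at sigma is kept ("less than" is strict)
  expect_identical(pruneCoefficients(c(1e-4, -1e-4, 5e-5), 1e-4),
                   c(1e-4, -1e-4, 0))
})

test_that("L-infinity normalization rescales the strongest regulator to 1", {
  expect_identical(normalizeLinf(c(0.5, -0.25, 0)), c(1, -0.5, 0))
  expect_identical(normalizeLinf(c(0, 0, 0)), c(0, 0, 0))
  set.seed(4)
  for (rep_ in 1:20) {
    v <- stats::rnorm(6)
    expect_equal(max(abs(normalizeLinf(v))), 1)
  }
})

test_that("regulator screening keeps exactly the true regulators on clean data", {
  bench <- generateBenchmark(delta = 0)
  for (i in c(1, 6, 7, 8)) {   # unit-weight, high-threshold and self-loop rules
    sc <- screenRegulators(bench$X, bench$Y[, i])
    expect_identical(which(sc$keep), unname(which(bench$gold[, i] != 0)))
  }
})

test_that("network inference recovers the benchmark exactly from clean data", {
  bench <- generateBenchmark(delta = 0)
  inf <- inferNetwork(t(bench$X), observedSuccessors = t(bench$Y))
  W <- weightMatrix(inf)
  expect_identical(sign(W), sign(bench$gold + 0))
  expect_true(all(abs(W) <= 1))
  nz <- apply(W, 2, function(col) max(abs(col)))
  expect_equal(unname(nz), rep(1, 9))  # every column normalized
  # rule polarity agrees with the weight sign on every edge
  for (i in 1:9) {
    r <- rules(inf)[[i]]
    for (j in seq_along(r@regulators)) {
      expect_identical(ifelse(r@negated[j], -1, 1),
                       unname(sign(W[r@regulators[j], i])))
    }
  }
})

test_that("constant genes produce constant rules and empty weight columns", {
  set.seed(77)
  B <- matrix(sample(0:1, 6 * 20, replace = TRUE), nrow = 6)
  B[3, ] <- 1L   # constitutively on
  B[5, ] <- 0L   # silent
  inf <- inferNetwork(B, screen = FALSE)
  W <- weightMatrix(inf)
  expect_identical(unname(W[, 3]), rep(0, 6))
  expect_identical(unname(W[, 5]), rep(0, 6))
  expect_identical(evalRule(rules(inf)[[3]], rep(0L, 6)), 1L)
  expect_identical(evalRule(rules(inf)[[5]], rep(0L, 6)), 0L)
  expect_true(inf@fits[[3]]$degenerate)
})

test_that("perturbation lets inference survive duplicated gene profiles", {
  set.seed(88)
  base <- sample(0:1, 30, replace = TRUE)
  B <- rbind(g1 = base, g2 = base, g3 = sample(0:1, 30, replace = TRUE),
             g4 = sample(0:1, 30, replace = TRUE))
  inf <- inferNetwork(B, perturb = TRUE, sigma = 1e-4, seed = 5)
  expect_s4_class(inf, "InferredNetwork")
  expect_identical(inf@metadata$failedGenes, character(0))
  # the perturbed design really is full rank
  X <- t(B[, -ncol(B)])
  Xp <- perturbDesign(X, 1e-4, seed = 5)
  expect_identical(qr(Xp)$rank, 4L)
})

test_that("small random networks are recovered exactly from full enumeration", {
  # scaled-down recovery property (the acceptance suite runs the full set)
  for (s in 1:5) {
    net <- randomBTN(8, maxInDegree = 3, seed = 400 + s)
    pairs <- enumerateStatePairs(net)
    inf <- inferNetwork(t(pairs$states), observedSuccessors = t(pairs$successors))
    expect_identical(sign(weightMatrix(inf)), sign(goldFromNetwork(net) + 0),
                     label = paste("network seed", 400 + s))
  }
})

test_that("state prediction is teacher-forced, never free-running", {
  net <- exampleNetwork9()
  pairs <- enumerateStatePairs(net)
  inf <- inferNetwork(t(pairs$states), observedSuccessors = t(pairs$successors))

  set.seed(6)
  B <- matrix(sample(0:1, 9 * 8, replace = TRUE), nrow = 9,
              dimnames = list(paste0("x", 1:9), NULL))
  pred <- predictStates(inf, B)
  expect_identical(dim(pred), c(9L, 7L))
  # column t depends only on observed column t
  for (t in 1:7)
    expect_identical(unname(pred[, t]), oracleSuccessor(ruleNetwork(inf), B[, t]))

  # all-constant network predicts constants
  constNet <- BooleanThresholdNetwork(
    lapply(1:9, function(i) ThresholdRule(threshold = 0)), paste0("x", 1:9))
  expect_true(all(predictStates(constNet, B) == 1L))

  expect_error(predictStates(inf, B[1:5, ]), "gene mismatch")
  rownames(B) <- paste0("g", 1:9)
  expect_error(predictStates(inf, B), "gene names")
})
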