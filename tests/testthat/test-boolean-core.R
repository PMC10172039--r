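test_that("rule evaluation follows the weighted-literal threshold semantics", {
  # single positive literal: fires iff gene 9 is on
  r <- ThresholdRule(9L, 1, FALSE, 1)
  expect_identical(evalRule(r, c(rep(0L, 8), 1L)), 1L)
  expect_identical(evalRule(r, rep(0L, 9)), 0L)

  # ties fire: empty rule with threshold 0 is the constant 1
  expect_identical(evalRule(ThresholdRule(threshold = 0), 0L), 1L)
  expect_identical(evalRule(ThresholdRule(threshold = 1), 0L), 0L)

  # mixed polarities and a non-unit weight: x5~ + 2*x6 + x9~ >= 2
  r7 <- ThresholdRule(c(5L, 6L, 9L), c(1, 2, 1), c(TRUE, FALSE, TRUE), 2)
  s <- rep(0L, 9); s[c(5, 6, 9)] <- 1L
  expect_identical(evalRule(r7, s), 1L)  # 0 + 2 + 0 >= 2
  s2 <- rep(0L, 9); s2[c(5, 9)] <- 1L
  expect_identical(evalRule(r7, s2), 0L)  # 0 + 0 + 0 < 2

  # malformed inputs are refused
  expect_error(evalRule(r7, rep(0L, 4)), "regulator index")
  expect_error(evalRule(r7, c(rep(0L, 8), 2L)), "0 or 1")
})

test_that("rule evaluation agrees with the literal-by-literal oracle", {
  set.seed(11)
  for (rep_ in 1:50) {
    r <- randomRule(6)
    for (j in 1:10) {
      s <- sample(0:1, 6, replace = TRUE)
      expect_identical(evalRule(r, s), oracleEvalRule(r, s))
    }
  }
})

test_that("synchronous update evaluates all genes on the same input state", {
  net <- exampleNetwork9()
  zero <- rep(0L, 9)
  succ <- syncUpdate(net, zero)
  expect_identical(unname(succ), oracleSuccessor(net, zero))
  # from all-zeros every fully-negated rule fires: x2 has 4 complements >= 4
  expect_identical(unname(succ[2]), 1L)
  # x1 ([x1 + x2 >= 1]) stays off
  expect_identical(unname(succ[1]), 0L)

  # determinism and purity
  expect_identical(syncUpdate(net, zero), syncUpdate(net, zero))

  # locality: x3 is regulated by x2, x5, x9 only; flipping x4 cannot move it
  s <- rep(0L, 9)
  sFlip <- s; sFlip[4] <- 1L
  expect_identical(syncUpdate(net, s)[3], syncUpdate(net, sFlip)[3])

  expect_error(syncUpdate(net, rep(0L, 5)), "network size")
})

test_that("trajectories iterate the synchronous update", {
  net <- exampleNetwork9()
  set.seed(21)
  init <- sample(0:1, 9, replace = TRUE)

  traj <- simulateTrajectory(net, init, steps = 20)
  expect_identical(dim(traj), c(9L, 21L))
  for (t in 1:20)
    expect_identical(unname(traj[, t + 1]), oracleSuccessor(net, traj[, t]))

  # one step is exactly init plus its successor
  t1 <- simulateTrajectory(net, init, steps = 1)
  expect_identical(unname(t1[, 2]), unname(syncUpdate(net, init)))

  # a fixed point yields a constant trajectory
  idnet <- BooleanThresholdNetwork(list(ThresholdRule(1L, 1, FALSE, 1)))
  tfix <- simulateTrajectory(idnet, 1L, steps = 5)
  expect_true(all(tfix == 1L))

  expect_error(simulateTrajectory(net, init, steps = 0), "steps")
})

test_that("state enumeration is canonical, complete and successor-consistent", {
  net <- exampleNetwork9()
  pairs <- enumerateStatePairs(net)
  expect_identical(nrow(pairs$states), 512L)
  expect_identical(ncol(pairs$states), 9L)

  # binary counting with gene 1 as least-significant bit
  expect_identical(unname(pairs$states[1, ]), rep(0L, 9))
  expect_identical(unname(pairs$states[2, ]), c(1L, rep(0L, 8)))
  expect_identical(unname(pairs$states[3, ]), c(0L, 1L, rep(0L, 7)))
  expect_identical(anyDuplicated(pairs$states), 0L)

  # successors match syncUpdate row by row (spot-check a sample plus ends)
  idx <- c(1, 2, 100, 256, 511, 512)
  for (j in idx)
    expect_identical(unname(pairs$successors[j, ]),
                     unname(syncUpdate(net, pairs$states[j, ])))

  # the augmented design has full column rank
  expect_identical(qr(cbind(pairs$states, 1))$rank, 10L)

  # tiny network: identity rule has fixed points 0 and 1
  id1 <- BooleanThresholdNetwork(list(ThresholdRule(1L, 1, FALSE, 1)))
  p1 <- enumerateStatePairs(id1)
  expect_identical(unname(p1$successors[, 1]), c(0L, 1L))

  big <- BooleanThresholdNetwork(
    lapply(1:21, function(i) ThresholdRule(1L, 1, FALSE, 1)))
  expect_error(enumerateStatePairs(big), "N <= 20")
})

test_that("coefficient aggregation reproduces the logistic decision rule", {
  # positive coefficient -> activating term, negative -> inhibiting with
  # flipped weight, threshold absorbs intercept and negative mass
  r <- ruleFromCoefficients(c(2, -3, 0), 1)
  expect_identical(r@regulators, c(1L, 2L))
  expect_identical(r@weights, c(2, 3))
  expect_identical(r@negated, c(FALSE, TRUE))
  expect_identical(r@threshold, 2)  # -1 - (-3)

  r0 <- ruleFromCoefficients(numeric(3), 0)
  expect_identical(length(r0@regulators), 0L)
  expect_identical(r0@threshold, 0)

  expect_error(ruleFromCoefficients(c(1, NA), 0), "finite")
  expect_error(ruleFromCoefficients(c(1, 2), Inf), "finite")
})

test_that("threshold rules are equivalent to the linear score indicator", {
  # the core equivalence: for any coefficients, the aggregated rule equals
  # [theta' x + theta0 >= 0] on every binary state
  set.seed(42)
  N <- 6
  states <- as.matrix(expand.grid(rep(list(0:1), N)))
  for (rep_ in 1:200) {
    theta <- round(stats::rnorm(N, sd = 2), 3)
    theta[sample.int(N, sample(0:3, 1))] <- 0
    theta0 <- round(stats::rnorm(1, sd = 2), 3)
    rule <- ruleFromCoefficients(theta, theta0)
    scores <- as.numeric(states %*% theta + theta0)
    want <- as.integer(scores >= 0)
    got <- vapply(seq_len(nrow(states)), function(j)
      evalRule(rule, states[j, ]), integer(1))
    expect_identical(got, want)
  }
})

test_that("rule truth tables are invariant to positive coefficient scaling", {
  set.seed(7)
  states <- as.matrix(expand.grid(rep(list(0:1), 5)))
  for (rep_ in 1:20) {
    theta <- stats::rnorm(5); theta0 <- stats::rnorm(1)
    c_ <- stats::runif(1, 0.1, 10)
    r1 <- ruleFromCoefficients(theta, theta0)
    r2 <- ruleFromCoefficients(c_ * theta, c_ * theta0)
    for (j in seq_len(nrow(states)))
      expect_identical(evalRule(r1, states[j, ]), evalRule(r2, states[j, ]))
  }
})

test_that("rule text rendering is deterministic and round-trippable", {
  genes <- paste0("x", 1:9)
  net <- exampleNetwork9()

  expect_identical(ruleToText(rules(net)[["x6"]], genes), "[x9 >= 1]")
  expect_identical(ruleToText(rules(net)[["x7"]], genes),
                   "[x5~ + 2*x6 + x9~ >= 2]")
  expect_identical(ruleToText(ThresholdRule(threshold = 0), genes),
                   "[0 >= 0]")

  # round trip on the benchmark rules and on random rules
  for (r in rules(net)) {
    back <- parseRule(ruleToText(r, genes), genes)
    expect_equal(back@regulators[order(back@regulators)],
                 r@regulators[order(r@regulators)])
    expect_identical(back@threshold, r@threshold)
  }
  set.seed(5)
  for (rep_ in 1:25) {
    r <- randomRule(9)
    back <- parseRule(ruleToText(r, genes), genes)
    o1 <- order(r@regulators); o2 <- order(back@regulators)
    expect_identical(back@regulators[o2], r@regulators[o1])
    expect_identical(back@weights[o2], r@weights[o1])
    expect_identical(back@negated[o2], r@negated[o1])
  }
})

test_that("invalid rules and networks are rejected by validity checks", {
  expect_error(ThresholdRule(c(1L, 1L), c(1, 1), c(FALSE, FALSE), 1), "unique")
  expect_error(ThresholdRule(1L, -2, FALSE, 1), "positive")
  expect_error(BooleanThresholdNetwork(list(ThresholdRule(5L, 1, FALSE, 1))),
               "beyond network size")
})
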