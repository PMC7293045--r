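test_that("e-step responsibilities match hand-normalized DM products", {
  pc <- makeToyPaired()[, 1:2]
  aR <- matrix(c(2, 1, 0.5, 0.5, 1, 2), 2, 3, byrow = TRUE)
  aA <- matrix(c(3, 1, 1, 3), 2, 2, byrow = TRUE)
  pi <- c(0.3, 0.7)
  es <- eStepJointDM(pc, aR, aA, pi)
  for (j in 1:2) {
    lw <- sapply(1:2, function(k) {
      log(pi[k]) + dmLogPmf(rnaCounts(pc)[, j], aR[k, ]) +
        dmLogPmf(adtCounts(pc)[, j], aA[k, ])
    })
    expect_equal(es$r[j, ], exp(lw) / sum(exp(lw)), tolerance = 1e-9)
  }
  expect_equal(es$logLik,
               sum(sapply(1:2, function(j) {
                 log(sum(sapply(1:2, function(k) {
                   pi[k] * exp(dmLogPmf(rnaCounts(pc)[, j], aR[k, ]) +
                                 dmLogPmf(adtCounts(pc)[, j], aA[k, ]))
                 })))
               })), tolerance = 1e-9)
})

test_that("e-step degenerate cases behave as required", {
  pc <- makeToyPaired()
  # K = 1: all responsibilities one
  es1 <- eStepJointDM(pc, matrix(1, 1, 3), matrix(1, 1, 2), 1)
  expect_equal(as.numeric(es1$r), rep(1, 3))
  # identical rows, uniform mixing: uniform responsibilities
  es2 <- eStepJointDM(pc, matrix(1, 3, 3), matrix(2, 3, 2), rep(1 / 3, 3))
  expect_equal(as.numeric(es2$r), rep(1 / 3, 9), tolerance = 1e-12)
  expect_error(eStepJointDM(pc, matrix(1, 2, 3), matrix(1, 2, 2), c(2, 1)),
               "pi")
})

test_that("m-step mixing proportions are responsibility means", {
  pc <- makeToyPaired()
  r <- matrix(c(0.9, 0.1, 0.3, 0.7, 0.5, 0.5), 3, 2, byrow = TRUE)
  ms <- mStepJointDM(pc, r, matrix(1, 2, 3), matrix(1, 2, 2))
  expect_equal(sum(ms$pi), 1, tolerance = 1e-12)
  expect_equal(ms$pi, colSums(r) / 3, tolerance = 1e-12)
  expect_true(all(ms$alphaRna > 0) && all(ms$alphaAdt > 0))
})

test_that("fixed-point alpha update matches a grid-search maximizer", {
  # single cluster, two genes: the weighted DM MLE found by the fixed
  # point should match an exhaustive grid search of the log-likelihood
  set.seed(10)
  n <- 60
  X <- sapply(seq_len(n), function(j) {
    p <- rbeta(1, 3, 2)
    rmultinom(1, 80, c(p, 1 - p))
  })
  pc <- PairedCounts(X, matrix(1, 1, n))  # ADT part inert (single marker)
  r <- matrix(1, n, 1)
  ms <- mStepJointDM(pc, r, matrix(c(2, 2), 1, 2), matrix(1, 1, 1))
  fitted <- ms$alphaRna[1, ]

  dmSum <- function(a) sum(apply(X, 2, function(x) dmLogPmf(x, a)))
  # coarse grid search, then refined around the coarse maximizer
  coarse <- expand.grid(a1 = seq(0.5, 12, length.out = 100),
                        a2 = seq(0.5, 12, length.out = 100))
  llC <- apply(coarse, 1, function(g) dmSum(c(g[1], g[2])))
  c0 <- unlist(coarse[which.max(llC), ])
  fine <- expand.grid(a1 = seq(0.9 * c0[1], 1.1 * c0[1], length.out = 81),
                      a2 = seq(0.9 * c0[2], 1.1 * c0[2], length.out = 81))
  llF <- apply(fine, 1, function(g) dmSum(c(g[1], g[2])))
  best <- unlist(fine[which.max(llF), ])
  # the fixed point matches the grid maximizer and its likelihood value
  expect_gte(dmSum(fitted), max(llF) - 1e-6)
  expect_lt(max(abs(fitted - best) / best), 1e-3 + 0.2 / 80)
})

test_that("hard responsibilities reduce to per-cluster unweighted fits", {
  sim <- quickSim(n = 15, G = 8, D = 3, seed = 12)
  z <- sim$truth$zTrue
  r <- matrix(0, length(z), 2)
  r[cbind(seq_along(z), z)] <- 1
  a0 <- matrix(1, 2, 8)
  msJoint <- mStepJointDM(sim$counts, r, a0, matrix(1, 2, 3))
  # fitting each cluster separately with all-one weights must agree
  for (k in 1:2) {
    sub <- sim$counts[, z == k]
    msK <- mStepJointDM(sub, matrix(1, sum(z == k), 1),
                        a0[k, , drop = FALSE], matrix(1, 1, 3))
    expect_equal(msJoint$alphaRna[k, ], msK$alphaRna[1, ], tolerance = 1e-6)
  }
})

test_that("EM is monotone, deterministic, and exact on independence data", {
  sim <- simulateREDM(simConfig(K = 2, cellsPerCluster = 50, G = 30, D = 8,
                                sigmaB = 0, seed = 13))
  f1 <- runJointDM(sim$counts, 2, emControl(seed = 1))
  f2 <- runJointDM(sim$counts, 2, emControl(seed = 1))
  expect_identical(clusterLabels(f1), clusterLabels(f2))
  expect_identical(f1@logPostTrace, f2@logPostTrace)
  expect_true(all(diff(f1@logPostTrace) >= -1e-10))
  expect_gte(adjustedRandIndex(clusterLabels(f1), sim$truth$zTrue), 0.95)
  expect_equal(rowSums(posteriorProbs(f1)), rep(1, 100), tolerance = 1e-9)
})

test_that("a starved cluster is left unchanged with a warning", {
  pc <- makeToyPaired()
  r <- matrix(c(1, 0, 1, 0, 1, 0), 3, 2, byrow = TRUE)
  a0 <- matrix(2, 2, 3)
  ws <- capture_warnings(ms <- mStepJointDM(pc, r, a0, matrix(1, 2, 2)))
  expect_match(ws, "responsibility", all = TRUE)
  expect_length(ws, 2)  # one per source block
  expect_equal(ms$alphaRna[2, ], a0[2, ])
})

test_that("large random effects favor the sampler over the independence EM", {
  # with sigma_b >= 1 the independence assumption is badly violated; over
  # 20 replicates the random-effects sampler should be at least as accurate
  # on average
  ariMcmc <- ariEm <- numeric(20)
  for (r in 1:20) {
    sim <- simulateREDM(simConfig(K = 3, cellsPerCluster = 40, sigmaB = 1,
                                  signalRna = "weak", signalAdt = "weak",
                                  seed = 800 + r))
    f1 <- runREDM(sim$counts, 3, mcmcControl(nIter = 250, nChains = 1,
                                             seed = r))
    f2 <- suppressWarnings(
      runJointDM(sim$counts, 3, emControl(maxIter = 30, maxInner = 50,
                                          seed = r)))
    ariMcmc[r] <- adjustedRandIndex(clusterLabels(f1), sim$truth$zTrue)
    ariEm[r] <- adjustedRandIndex(clusterLabels(f2), sim$truth$zTrue)
  }
  expect_gt(mean(ariMcmc), mean(ariEm))
})
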