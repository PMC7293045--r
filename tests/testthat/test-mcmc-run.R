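test_that("chains are reproducible bit for bit given the seed", {
  sim <- quickSim(n = 25, G = 20, D = 6, seed = 2)
  init <- initialModelParams(sim$counts, 2, seed = 1)
  ctrl <- mcmcControl(nIter = 40, nChains = 1, seed = 7)
  c1 <- runREDMChain(sim$counts, 2, init, ctrl, chainSeed = 7)
  c2 <- runREDMChain(sim$counts, 2, init, ctrl, chainSeed = 7)
  expect_identical(c1@zSamples, c2@zSamples)
  expect_identical(c1@logPost, c2@logPost)
  expect_identical(c1@finalParams@alphaRna, c2@finalParams@alphaRna)
})

test_that("a single-cluster chain keeps all labels constant", {
  sim <- quickSim(n = 15, G = 10, D = 4, seed = 3)
  fit <- runREDMChain(sim$counts, 1,
                      initialModelParams(sim$counts, 1, seed = 1),
                      mcmcControl(nIter = 30, nChains = 1, seed = 1),
                      chainSeed = 1)
  expect_true(all(fit@zSamples == 1L))
})

test_that("the log-posterior trace reaches a plateau", {
  sim <- quickSim(n = 40, seed = 4)
  fit <- runREDMChain(sim$counts, 2,
                      initialModelParams(sim$counts, 2, seed = 1),
                      mcmcControl(nIter = 200, nChains = 1, seed = 1),
                      chainSeed = 1)
  lp <- fit@logPost
  lastDecile <- lp[seq.int(floor(0.9 * length(lp)) + 1, length(lp))]
  expect_gt(mean(lastDecile), max(lp) - 0.01 * abs(max(lp)))
})

test_that("runREDM returns coherent posterior summaries", {
  sim <- quickSim(n = 30, seed = 5)
  fit <- runREDM(sim$counts, 2, mcmcControl(nIter = 80, nChains = 2, seed = 1))
  post <- posteriorProbs(fit)
  expect_equal(rowSums(post), rep(1, ncol(sim$counts)), tolerance = 1e-9)
  expect_identical(clusterLabels(fit),
                   as.integer(max.col(post, ties.method = "first")))
  expect_true(fit@selectedChain %in% 1:2)
  # maximum-likelihood chain selection: selected chain attains the largest
  # maximum recorded log-posterior
  chains <- attr(fit, "chains")
  peaks <- vapply(chains, function(ch) max(ch@logPost), 0)
  expect_equal(fit@selectedChain, which.max(peaks))
})

test_that("runREDM validates K and reduces to one chain cleanly", {
  sim <- quickSim(n = 10, G = 10, D = 4, seed = 6)
  expect_error(runREDM(sim$counts, 0), "K must lie")
  expect_error(runREDM(sim$counts, 1000), "K must lie")
  fit <- runREDM(sim$counts, 2, mcmcControl(nIter = 30, nChains = 1, seed = 2))
  expect_s4_class(fit, "DMClusterResult")
})

test_that("flagVagueCells flags the requested count with index tie-breaks", {
  post <- matrix(0, 100, 2)
  post[, 1] <- 1  # every cell fully confident: pure tie-break on index
  res <- new("DMClusterResult", labels = rep(1L, 100), posterior = post,
             selectedChain = 1L, logPostTrace = 0, method = "redm",
             paramsHat = DMParams(matrix(1, 2, 2), matrix(1, 2, 2),
                                  z = rep(1L, 100), b = rep(1, 100)))
  flags <- flagVagueCells(res, 0.05)
  expect_identical(which(flags), 1:5)
  expect_equal(sum(flagVagueCells(res, 0.031)), 3L)
  expect_error(flagVagueCells(res, 0), "fraction")
  expect_error(flagVagueCells(res, 1), "fraction")

  # least-confident cells are flagged first
  post2 <- cbind(c(0.51, 0.9, 0.55, 1, 0.99), c(0.49, 0.1, 0.45, 0, 0.01))
  res2 <- new("DMClusterResult", labels = rep(1L, 5), posterior = post2,
              selectedChain = 1L, logPostTrace = 0, method = "redm",
              paramsHat = DMParams(matrix(1, 2, 2), matrix(1, 2, 2),
                                   z = rep(1L, 5), b = rep(1, 5)))
  expect_identical(which(flagVagueCells(res2, 0.45)), c(1L, 3L))
})

test_that("boundary cells between overlapping clusters are vague-enriched", {
  # two mildly separated clusters (2-fold elevation on a few features):
  # a minority of cells is genuinely ambiguous and should be
  # over-represented among flagged cells
  base <- rep(1, 20)
  aR <- rbind(base, base)
  aR[1, 1:3] <- aR[1, 1:3] * 2
  aR[2, 4:6] <- aR[2, 4:6] * 2
  aA <- matrix(3, 2, 6)
  aA[1, 1] <- 6
  aA[2, 2] <- 6
  sim <- simulateREDM(simConfig(K = 2, cellsPerCluster = 60, G = 20, D = 6,
                                sigmaB = 0, alphaRna = aR, alphaAdt = aA,
                                seed = 31))
  fit <- runREDM(sim$counts, 2,
                 mcmcControl(nIter = 300, nChains = 2, seed = 3))
  flags <- flagVagueCells(fit, 0.1)
  expect_equal(sum(flags), floor(0.1 * 120))
  # ground-truth responsibilities under the generating parameters mark the
  # genuinely ambiguous cells
  tp <- sim$truth$paramsTrue
  es <- eStepJointDM(sim$counts, tp@alphaRna, tp@alphaAdt, c(0.5, 0.5))
  trueUncertain <- apply(es$r, 1, max) < 0.7
  expect_gt(sum(trueUncertain), 3)
  expect_gte(mean(flags[trueUncertain]), 2 * mean(flags))
})

test_that("with vanishing random-effect variance the sampler matches the EM fit", {
  sim <- simulateREDM(simConfig(K = 2, cellsPerCluster = 50, G = 30, D = 8,
                                sigmaB = 0, seed = 41))
  mcmcFit <- runREDM(sim$counts, 2,
                     mcmcControl(nIter = 150, nChains = 1, seed = 1,
                                 sigmaB2Mode = "fixed", sigmaB2Fixed = 1e-6))
  emFit <- runJointDM(sim$counts, 2, emControl(seed = 1))
  expect_gte(adjustedRandIndex(clusterLabels(mcmcFit),
                               clusterLabels(emFit)), 0.95)
})
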