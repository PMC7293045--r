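test_that("gibbsUpdateZ is deterministic with one cluster and symmetric with two", {
  pc <- makeToyPaired()
  par1 <- DMParams(matrix(1, 1, 3), matrix(2, 1, 2), z = rep(1L, 3))
  expect_identical(gibbsUpdateZ(pc, par1), rep(1L, 3))

  # identical rows: empirical assignment fraction near 1/2 per cluster
  par2 <- DMParams(matrix(1, 2, 3), matrix(2, 2, 2), z = rep(1L, 3))
  set.seed(1)
  draws <- replicate(600, gibbsUpdateZ(pc, par2))
  expect_equal(mean(draws == 1L), 0.5, tolerance = 0.05)
})

test_that("gibbs draws recover well-separated cluster structure", {
  sim <- quickSim(seed = 5)
  truthPar <- sim$truth$paramsTrue
  set.seed(2)
  hits <- replicate(20, mean(gibbsUpdateZ(sim$counts, truthPar) ==
                               sim$truth$zTrue))
  # labels may come out permuted only if clusters were swapped wholesale;
  # with the true parameters the match should be essentially perfect
  expect_gte(mean(hits), 0.99)
})

test_that("zero-step Metropolis proposals are always accepted and change nothing", {
  pc <- makeToyPaired()
  par <- makeToyParams()
  set.seed(1)
  ua <- mhUpdateAlpha(pc, par, "rna", step = 0)
  expect_equal(ua$params@alphaRna, par@alphaRna)
  expect_equal(ua$nAccept, ua$nPropose)
  ub <- mhUpdateB(pc, par, step = 0)
  expect_equal(ub$params@b, par@b)
  expect_equal(ub$nAccept, ub$nPropose)
})

test_that("alpha acceptance log-ratios equal brute-force posterior differences", {
  pc <- makeToyPaired()[, 1:2]
  par <- DMParams(matrix(c(2, 1, 0.5, 0.5, 1, 2), 2, 3, byrow = TRUE),
                  matrix(c(3, 1, 1, 3), 2, 2, byrow = TRUE),
                  z = c(1L, 2L), b = c(1, 0.7), sigmaB2 = 0.4)
  for (source in c("rna", "adt")) {
    set.seed(11)
    res <- mhUpdateAlpha(pc, par, source, step = 0.4, diagnostics = TRUE)
    state <- par
    for (r in seq_len(nrow(res$trace))) {
      tr <- res$trace[r, ]
      prop <- state
      if (source == "rna") prop@alphaRna[tr$k, tr$i] <- tr$proposed
      else prop@alphaAdt[tr$k, tr$i] <- tr$proposed
      cur <- if (source == "rna") state@alphaRna[tr$k, tr$i]
             else state@alphaAdt[tr$k, tr$i]
      bruteforce <- refCompleteLogPost(pc, prop) -
        refCompleteLogPost(pc, state) + log(tr$proposed / cur)
      expect_equal(tr$log_ratio, bruteforce, tolerance = 1e-9)
      if (tr$accepted == 1) state <- prop
    }
    # replayed end state must equal the sweep's end state
    endBlock <- if (source == "rna") res$params@alphaRna else res$params@alphaAdt
    stateBlock <- if (source == "rna") state@alphaRna else state@alphaAdt
    expect_equal(endBlock, stateBlock, tolerance = 1e-12)
  }
})

test_that("b acceptance log-ratios match single-cell posterior re-evaluation", {
  pc <- makeToyPaired()[, 1, drop = FALSE]
  par <- DMParams(matrix(c(2, 1, 0.5), 1, 3), matrix(c(3, 1), 1, 2),
                  z = 1L, b = 1.2, sigmaB2 = 0.6)
  set.seed(21)
  res <- mhUpdateB(pc, par, step = 0.5, diagnostics = TRUE)
  tr <- res$trace[1, ]
  prop <- par
  prop@b <- tr$proposed
  bruteforce <- refCompleteLogPost(pc, prop) - refCompleteLogPost(pc, par) +
    log(tr$proposed / par@b)
  expect_equal(tr$log_ratio, bruteforce, tolerance = 1e-9)
})

test_that("a tight random-effect prior pins b near one", {
  sim <- quickSim(n = 20, seed = 8)
  par <- initialModelParams(sim$counts, 2, seed = 1)
  par@sigmaB2 <- 1e-8
  set.seed(3)
  for (t in 1:50) par <- mhUpdateB(sim$counts, par, step = 0.05)$params
  expect_true(all(abs(par@b - 1) < 1e-3))
})

test_that("sigma_b^2 conjugate update concentrates correctly", {
  # all b = 1: posterior InverseGamma(a0 + C/2, b0), mean ~ b0/(C/2)
  par <- DMParams(matrix(1, 1, 2), matrix(1, 1, 2), z = rep(1L, 2000),
                  b = rep(1, 2000), sigmaB2 = 1)
  pc <- NULL  # update does not touch the data
  set.seed(4)
  draws <- replicate(200, updateSigmaB2(pc, par)@sigmaB2)
  expect_lt(max(draws), 1e-3)

  # b ~ LogNormal(0, 0.25): posterior mean of sigma_b^2 near 0.25
  set.seed(5)
  par@b <- exp(rnorm(2000, 0, 0.5))
  draws <- replicate(300, updateSigmaB2(pc, par)@sigmaB2)
  expect_gt(mean(draws), 0.2)
  expect_lt(mean(draws), 0.3)

  # fixed mode returns the stored value unchanged
  par@sigmaB2 <- 0.123
  expect_equal(updateSigmaB2(pc, par, mode = "fixed")@sigmaB2, 0.123)
})

test_that("adaptive steps land in a healthy acceptance window", {
  sim <- quickSim(n = 30, seed = 9)
  fit <- runREDMChain(sim$counts, 2,
                      initialModelParams(sim$counts, 2, seed = 1),
                      mcmcControl(nIter = 200, nChains = 1, seed = 1),
                      chainSeed = 1)
  expect_true(all(fit@acceptRates >= 0.15 & fit@acceptRates <= 0.50))
})
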