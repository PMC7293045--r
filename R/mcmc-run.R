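#' Run one Metropolis-within-Gibbs chain
#'
#' Executes `nIter` fixed-order sweeps (labels, RNA alpha block, ADT alpha
#' block, random effects, sigma_b^2) from the supplied initial state. The
#' complete log-posterior is recorded at each sweep; proposal step sizes are
#' adapted toward 30% acceptance during burn-in only and frozen afterwards.
#' Post-burn-in sweeps accumulate posterior means of the alpha blocks and
#' `b`, returned in `finalParams`. The chain is fully reproducible given
#' `chainSeed`.
#'
#' @inheritParams dmLogLikMatrix
#' @param K number of clusters.
#' @param init initial [DMParams-class] state (see
#'   [initialModelParams()]).
#' @param control a [mcmcControl()] list.
#' @param chainSeed integer seed for this chain.
#' @return A [DMChain-class] object.
#' @export
runREDMChain <- function(data, K, init, control = mcmcControl(),
                         chainSeed = control$seed) {
  .checkDims(data, init)
  if (nrow(init@alphaRna) != K) stop("init has the wrong number of clusters")
  set.seed(as.integer(chainSeed))
  C <- ncol(data)
  nIter <- control$nIter
  burnIn <- as.integer(floor(control$burnInFraction * nIter))
  params <- init
  if (control$sigmaB2Mode == "fixed") params@sigmaB2 <- control$sigmaB2Fixed
  stepA1 <- control$rwStepAlpha
  stepA2 <- control$rwStepAlpha
  stepB <- control$rwStepB
  coefConst <- sum(.dmCoef(data@rnaCounts)) + sum(.dmCoef(data@adtCounts))

  zSamples <- matrix(0L, nIter, C)
  logPost <- numeric(nIter)
  sigmaTrace <- numeric(nIter)
  acc <- c(alpha_rna = 0, alpha_adt = 0, b = 0)
  prop <- c(alpha_rna = 0, alpha_adt = 0, b = 0)
  alphaRnaSum <- matrix(0, K, ncol(init@alphaRna))
  alphaAdtSum <- matrix(0, K, ncol(init@alphaAdt))
  bSum <- numeric(C)
  nKept <- 0L

  for (t in seq_len(nIter)) {
    W <- dmLogLikMatrix(data, params, includeCoef = FALSE)
    params@z <- gibbsUpdateZ(data, params, W = W)
    lb <- log(params@b)
    logPost[t] <- sum(W[cbind(seq_len(C), params@z)]) + coefConst +
      sum(-lb - lb^2 / (2 * params@sigmaB2)) -
      C / 2 * log(params@sigmaB2)
    if (!is.finite(logPost[t]))
      stop("complete log-posterior became non-finite at sweep ", t)

    u1 <- mhUpdateAlpha(data, params, "rna", stepA1)
    params <- u1$params
    u2 <- mhUpdateAlpha(data, params, "adt", stepA2)
    params <- u2$params
    u3 <- mhUpdateB(data, params, stepB)
    params <- u3$params
    params <- updateSigmaB2(data, params, mode = control$sigmaB2Mode)

    acc <- acc + c(u1$nAccept, u2$nAccept, u3$nAccept)
    prop <- prop + c(u1$nPropose, u2$nPropose, u3$nPropose)
    if (control$adapt && t <= burnIn) {
      gain <- 1 / sqrt(t)
      if (u1$nPropose > 0)
        stepA1 <- stepA1 * exp(gain * (u1$nAccept / u1$nPropose - 0.3))
      if (u2$nPropose > 0)
        stepA2 <- stepA2 * exp(gain * (u2$nAccept / u2$nPropose - 0.3))
      stepB <- stepB * exp(gain * (u3$nAccept / u3$nPropose - 0.3))
    }

    zSamples[t, ] <- params@z
    sigmaTrace[t] <- params@sigmaB2
    if (t > burnIn) {
      alphaRnaSum <- alphaRnaSum + params@alphaRna
      alphaAdtSum <- alphaAdtSum + params@alphaAdt
      bSum <- bSum + params@b
      nKept <- nKept + 1L
    }
  }

  final <- params
  final@alphaRna <- alphaRnaSum / nKept
  final@alphaAdt <- alphaAdtSum / nKept
  final@b <- bSum / nKept
  rates <- ifelse(prop > 0, acc / prop, 0)
  names(rates) <- names(prop)
  new("DMChain", zSamples = zSamples, logPost = logPost,
      sigmaB2Samples = sigmaTrace, acceptRates = rates,
      finalParams = final, burnIn = burnIn)
}

#' Joint clustering by the random-effects Dirichlet-multinomial sampler
#'
#' Fits the joint mixture model with cell-specific log-normal random
#' effects by running `nChains` Metropolis-within-Gibbs chains from
#' independent K-means-seeded initializations and selecting the chain whose
#' maximum recorded complete log-posterior is largest. The per-cell
#' posterior cluster probabilities are the post-burn-in assignment
#' frequencies of the selected chain; hard labels are the row-wise argmax
#' (ties broken by lowest cluster index).
#'
#' @inheritParams runREDMChain
#' @return A [DMClusterResult-class] object. The chain traces are attached
#'   as `attr(result, "chains")`.
#' @examples
#' sim <- simulateREDM(simConfig(K = 2, cellsPerCluster = c(30, 30),
#'                               G = 40, D = 8, seed = 1))
#' fit <- runREDM(sim$counts, K = 2,
#'                control = mcmcControl(nIter = 100, nChains = 1, seed = 1))
#' table(clusterLabels(fit), sim$truth$zTrue)
#' @export
runREDM <- function(data, K, control = mcmcControl()) {
  K <- as.integer(K)
  if (K < 1L || K > ncol(data))
    stop("K must lie between 1 and the number of cells")
  set.seed(control$seed)
  chainSeeds <- sample.int(.Machine$integer.max, control$nChains)
  chains <- vector("list", control$nChains)
  for (ch in seq_len(control$nChains)) {
    init <- initialModelParams(data, K, seed = chainSeeds[ch])
    if (control$sigmaB2Mode == "fixed") init@sigmaB2 <- control$sigmaB2Fixed
    chains[[ch]] <- runREDMChain(data, K, init, control,
                                 chainSeed = chainSeeds[ch])
  }
  best <- which.max(vapply(chains, function(x) max(x@logPost), 0))
  sel <- chains[[best]]
  keep <- seq.int(sel@burnIn + 1L, nrow(sel@zSamples))
  C <- ncol(sel@zSamples)
  post <- matrix(0, C, K)
  for (t in keep)
    post[cbind(seq_len(C), sel@zSamples[t, ])] <-
      post[cbind(seq_len(C), sel@zSamples[t, ])] + 1
  post <- post / length(keep)
  labels <- max.col(post, ties.method = "first")
  pars <- sel@finalParams
  pars@z <- as.integer(labels)
  res <- new("DMClusterResult", labels = as.integer(labels),
             posterior = post, selectedChain = as.integer(best),
             logPostTrace = sel@logPost, paramsHat = pars,
             method = "redm")
  attr(res, "chains") <- chains
  res
}

#' Flag cells with uncertain (vague) cluster assignment
#'
#' Soft clustering makes assignment confidence explicit: a cell whose
#' largest posterior cluster probability is low sits between clusters.
#' This flags the `floor(fraction * C)` cells with the smallest
#' row-maximum posterior probability (ties broken by cell index), e.g. the
#' lowest 5% when `fraction = 0.05`.
#'
#' @param result a [DMClusterResult-class] object.
#' @param fraction fraction of cells to flag, in (0, 1).
#' @return Logical vector of length C, `TRUE` for flagged cells.
#' @export
flagVagueCells <- function(result, fraction = 0.05) {
  if (length(fraction) != 1L || !is.finite(fraction) ||
      fraction <= 0 || fraction >= 1)
    stop("fraction must be a single number in (0, 1)")
  pmax <- apply(posteriorProbs(result), 1L, max)
  C <- length(pmax)
  nFlag <- as.integer(floor(fraction * C))
  flags <- rep(FALSE, C)
  if (nFlag > 0L)
    flags[order(pmax, seq_len(C))[seq_len(nFlag)]] <- TRUE
  flags
}
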