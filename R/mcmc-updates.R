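#' Control parameters for the Metropolis-within-Gibbs sampler
#'
#' @param nIter total sweeps per chain (default 500).
#' @param nChains number of independently initialized chains (default 3);
#'   the chain attaining the largest complete log-posterior is selected.
#' @param burnInFraction fraction of sweeps discarded as burn-in, in (0,1)
#'   (default 0.5); at least one retained sweep is required.
#' @param rwStepAlpha initial standard deviation of the log-scale random
#'   walk on Dirichlet parameters.
#' @param rwStepB initial standard deviation of the log-scale random walk on
#'   the cell random effects.
#' @param adapt adapt the step sizes toward 30% acceptance during burn-in
#'   (Robbins-Monro); steps are frozen after burn-in so the post-burn-in
#'   chain is a valid Markov chain.
#' @param seed integer seed controlling all chain randomness.
#' @param sigmaB2Mode `"sample"` draws sigma_b^2 from its conjugate
#'   inverse-gamma full conditional each sweep; `"fixed"` keeps it at
#'   `sigmaB2Fixed`.
#' @param sigmaB2Fixed value used in `"fixed"` mode and as the initial
#'   sigma_b^2 in `"sample"` mode.
#' @return A validated list of class `"redm_mcmc_control"`.
#' @export
mcmcControl <- function(nIter = 500L, nChains = 3L, burnInFraction = 0.5,
                        rwStepAlpha = 0.2, rwStepB = 0.1, adapt = TRUE,
                        seed = 1L, sigmaB2Mode = c("sample", "fixed"),
                        sigmaB2Fixed = 1) {
  sigmaB2Mode <- match.arg(sigmaB2Mode)
  nIter <- as.integer(nIter)
  nChains <- as.integer(nChains)
  if (nIter < 2L) stop("nIter must be at least 2")
  if (nChains < 1L) stop("nChains must be at least 1")
  if (burnInFraction <= 0 || burnInFraction >= 1)
    stop("burnInFraction must lie in (0, 1)")
  if (floor(burnInFraction * nIter) >= nIter)
    stop("burn-in must leave at least one retained sweep")
  if (rwStepAlpha < 0 || rwStepB < 0) stop("step sizes must be non-negative")
  if (sigmaB2Fixed <= 0) stop("sigmaB2Fixed must be positive")
  structure(list(nIter = nIter, nChains = nChains,
                 burnInFraction = burnInFraction,
                 rwStepAlpha = rwStepAlpha, rwStepB = rwStepB,
                 adapt = isTRUE(adapt), seed = as.integer(seed),
                 sigmaB2Mode = sigmaB2Mode, sigmaB2Fixed = sigmaB2Fixed),
            class = "redm_mcmc_control")
}

#' Gibbs update of all cluster labels
#'
#' Draws every `z[j]` from its full conditional: the categorical
#' distribution obtained by softmax of [cellClusterLogWeights()] under a
#' uniform prior over clusters. All cells are updated in one sweep in
#' ascending cell order (a single joint draw, since labels are
#' conditionally independent given the parameters).
#'
#' @inheritParams dmLogLikMatrix
#' @param W optional precomputed C x K log-weight matrix (coefficients may
#'   be included or not; they cancel row-wise).
#' @return Integer label vector of length C.
#' @export
gibbsUpdateZ <- function(data, params, W = NULL) {
  if (is.null(W)) W <- dmLogLikMatrix(data, params, includeCoef = FALSE)
  P <- .softmaxRows(W)
  C <- nrow(P)
  K <- ncol(P)
  if (K == 1L) return(rep(1L, C))
  cum <- t(apply(P, 1L, cumsum))
  u <- stats::runif(C)
  pmin(K, as.integer(rowSums(cum < u) + 1L))
}

#' Metropolis update of one source's Dirichlet parameter block
#'
#' One sweep of element-wise multiplicative log-normal random-walk
#' proposals over the K x F parameter block of the chosen source,
#' `alpha' = alpha * exp(eps)`, `eps ~ N(0, step^2)`. Each element is
#' accepted with probability `min(1, exp(delta))` where `delta` is the
#' change in the complete log-posterior (only cells currently assigned to
#' the row's cluster contribute) plus the proposal-asymmetry correction
#' `log(alpha'/alpha)`. Rows of currently empty clusters are frozen.
#'
#' @inheritParams dmLogLikMatrix
#' @param source `"rna"` or `"adt"`.
#' @param step random-walk standard deviation on the log scale; `step = 0`
#'   leaves the block unchanged.
#' @param diagnostics also return the per-element proposal trace (used by
#'   validity checks).
#' @return A list with the updated [DMParams-class] object (`params`),
#'   acceptance and proposal counts (`nAccept`, `nPropose`) and, when
#'   requested, the proposal `trace`.
#' @export
mhUpdateAlpha <- function(data, params, source = c("rna", "adt"), step,
                          diagnostics = FALSE) {
  source <- match.arg(source)
  .checkDims(data, params)
  X <- if (source == "rna") data@rnaCounts else data@adtCounts
  A <- if (source == "rna") params@alphaRna else params@alphaAdt
  res <- cc_mh_alpha_sweep(X, A, params@z, params@b, step, diagnostics)
  if (source == "rna") params@alphaRna <- res$alpha
  else params@alphaAdt <- res$alpha
  out <- list(params = params, nAccept = res$n_accept,
              nPropose = res$n_propose)
  if (diagnostics) out$trace <- as.data.frame(res$trace)
  out
}

#' Metropolis update of the cell random effects
#'
#' One sweep of per-cell multiplicative log-normal random-walk proposals on
#' `b[j]`. The acceptance log-ratio uses only cell `j`'s two DM terms and
#' its prior term `-log b_j - (log b_j)^2/(2 sigma_b^2)`, plus the
#' asymmetry correction.
#'
#' @inheritParams mhUpdateAlpha
#' @return A list with updated `params`, `nAccept`, `nPropose` and
#'   optionally `trace`.
#' @export
mhUpdateB <- function(data, params, step, diagnostics = FALSE) {
  .checkDims(data, params)
  res <- cc_mh_b_sweep(data@rnaCounts, data@adtCounts, params@alphaRna,
                       params@alphaAdt, params@z, params@b, params@sigmaB2,
                       step, diagnostics)
  params@b <- res$b
  out <- list(params = params, nAccept = res$n_accept,
              nPropose = res$n_propose)
  if (diagnostics) out$trace <- as.data.frame(res$trace)
  out
}

#' Conjugate update of the random-effect variance
#'
#' With `log(b_j) ~ N(0, sigma_b^2)` i.i.d. and a weak
#' `InverseGamma(a0, b0)` prior, the full conditional of sigma_b^2 is
#' `InverseGamma(a0 + C/2, b0 + sum(log b)^2 / 2)`, sampled as the inverse
#' of a gamma draw. In `"fixed"` mode the stored value is returned
#' unchanged.
#'
#' @inheritParams dmLogLikMatrix
#' @param mode `"sample"` or `"fixed"`.
#' @param a0,b0 inverse-gamma hyperparameters (default 0.01, weakly
#'   informative).
#' @return The updated [DMParams-class] object.
#' @export
updateSigmaB2 <- function(data, params, mode = c("sample", "fixed"),
                          a0 = 0.01, b0 = 0.01) {
  mode <- match.arg(mode)
  if (mode == "fixed") return(params)
  C <- length(params@b)
  shape <- a0 + C / 2
  rate <- b0 + sum(log(params@b)^2) / 2
  params@sigmaB2 <- 1 / stats::rgamma(1L, shape = shape, rate = rate)
  params
}
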