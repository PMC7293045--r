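#' Control parameters for the EM fit of the independence model
#'
#' @param maxIter maximum EM iterations (default 200).
#' @param tol relative change in observed-data log-likelihood below which
#'   EM stops (default 1e-6).
#' @param maxInner cap on fixed-point iterations inside each M-step block
#'   (default 1000; the iteration converges linearly, so cold starts can
#'   need many steps while warm starts exit almost immediately).
#' @param seed integer seed for the K-means initialization.
#' @return A validated list of class `"redm_em_control"`.
#' @export
emControl <- function(maxIter = 200L, tol = 1e-6, maxInner = 1000L,
                      seed = 1L) {
  maxIter <- as.integer(maxIter)
  maxInner <- as.integer(maxInner)
  if (maxIter < 1L) stop("maxIter must be at least 1")
  if (maxInner < 1L) stop("maxInner must be at least 1")
  if (tol <= 0) stop("tol must be positive")
  structure(list(maxIter = maxIter, tol = tol, maxInner = maxInner,
                 seed = as.integer(seed)),
            class = "redm_em_control")
}

#' E-step of the joint independence model
#'
#' Computes the responsibility matrix `r[j, k]` proportional to
#' `pi_k * exp(dm(x_j_rna | alphaRna[k,]) + dm(x_j_adt | alphaAdt[k,]))`,
#' in log space with row-wise max subtraction, and the observed-data
#' log-likelihood `sum_j logSumExp` of the unnormalized rows (multinomial
#' coefficients included).
#'
#' @param data a [PairedCounts-class] object.
#' @param alphaRna,alphaAdt K x G and K x D positive parameter blocks.
#' @param pi mixing proportions summing to one.
#' @return A list with `r` (C x K responsibilities, rows summing to one)
#'   and `logLik` (scalar).
#' @export
eStepJointDM <- function(data, alphaRna, alphaAdt, pi) {
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-8)
    stop("pi must be a probability vector summing to one")
  one <- rep(1, ncol(data))
  L <- cc_dm_loglik_mat(data@rnaCounts, as.matrix(alphaRna), one) +
    cc_dm_loglik_mat(data@adtCounts, as.matrix(alphaAdt), one)
  L <- sweep(L, 2L, log(pi), "+")
  L <- L + .dmCoef(data@rnaCounts) + .dmCoef(data@adtCounts)
  m <- apply(L, 1L, max)
  E <- exp(L - m)
  s <- rowSums(E)
  list(r = E / s, logLik = sum(m + log(s)))
}

# Responsibility-weighted Dirichlet-multinomial maximum likelihood for the
# rows of one parameter block, by the standard damped fixed-point update
#   a_i <- a_i * sum_j r_j [psi(x_ij + a_i) - psi(a_i)]
#              / sum_j r_j [psi(T_j + |a|) - psi(|a|)]
# warm-started from the current value. Each update increases the weighted
# DM log-likelihood; iteration stops at relative change < 1e-8 or after
# `innerMax` steps (the iteration is linearly convergent, so warm starts
# finish in a handful of steps while cold starts may need hundreds).
# Entries are floored at 1e-6 to preserve positivity.
.dmFixedPointBlock <- function(X, R, alpha, innerMax = 1000L) {
  Tt <- colSums(X)
  K <- nrow(alpha)
  for (k in seq_len(K)) {
    r <- R[, k]
    if (sum(r) < 1e-8) {
      warning("cluster ", k, " has vanishing responsibility; ",
              "its parameters were left unchanged")
      next
    }
    a <- alpha[k, ]
    num0 <- as.vector((X > 0) %*% r) # guard: features never observed
    for (it in seq_len(innerMax)) {
      S <- sum(a)
      num <- as.vector(digamma(X + a) %*% r) - sum(r) * digamma(a)
      den <- sum(r * digamma(Tt + S)) - sum(r) * digamma(S)
      # lower floor preserves positivity; upper cap guards the divergent
      # MLE of underdispersed data (alpha -> infinity)
      aNew <- pmin(pmax(a * num / den, 1e-6), 1e8)
      aNew[num0 == 0] <- 1e-6
      if (max(abs(aNew - a) / pmax(a, 1e-12)) < 1e-8) {
        a <- aNew
        break
      }
      a <- aNew
    }
    alpha[k, ] <- a
  }
  alpha
}

#' M-step of the joint independence model
#'
#' Updates the mixing proportions `pi_k = sum_j r[j,k] / C` and each
#' cluster's Dirichlet parameter rows by responsibility-weighted DM maximum
#' likelihood via a damped fixed-point iteration (warm-started from the
#' current values). A cluster whose total responsibility is below 1e-8 is
#' left unchanged with a warning.
#'
#' @inheritParams eStepJointDM
#' @param r C x K responsibility matrix.
#' @param maxInner cap on fixed-point iterations per block.
#' @return A list with updated `alphaRna`, `alphaAdt` and `pi`.
#' @export
mStepJointDM <- function(data, r, alphaRna, alphaAdt, maxInner = 1000L) {
  r <- as.matrix(r)
  pi <- colSums(r) / nrow(r)
  list(alphaRna = .dmFixedPointBlock(data@rnaCounts, r, as.matrix(alphaRna),
                                     innerMax = maxInner),
       alphaAdt = .dmFixedPointBlock(data@adtCounts, r, as.matrix(alphaAdt),
                                     innerMax = maxInner),
       pi = pi)
}

#' Joint clustering by EM under the independence model
#'
#' Fits the independence variant of the joint model — both sources
#' Dirichlet-multinomial mixtures sharing one set of cluster labels, no
#' cell random effects — by EM with mixing proportions, from a K-means plus
#' method-of-moments initialization. The observed-data log-likelihood is
#' non-decreasing across iterations; convergence is declared when its
#' relative change falls below `tol`.
#'
#' @inheritParams runREDM
#' @param control an [emControl()] list.
#' @return A [DMClusterResult-class] object whose posterior matrix holds
#'   the final responsibilities. The fitted mixing proportions are attached
#'   as `attr(result, "pi")`.
#' @export
runJointDM <- function(data, K, control = emControl()) {
  K <- as.integer(K)
  if (K < 1L || K > ncol(data))
    stop("K must lie between 1 and the number of cells")
  init <- initialModelParams(data, K, seed = control$seed)
  alphaRna <- init@alphaRna
  alphaAdt <- init@alphaAdt
  pi <- tabulate(init@z, K) / length(init@z)
  pi <- pmax(pi, 1e-8)
  pi <- pi / sum(pi)

  ll <- -Inf
  trace <- numeric(0)
  r <- NULL
  for (it in seq_len(control$maxIter)) {
    es <- eStepJointDM(data, alphaRna, alphaAdt, pi)
    r <- es$r
    if (es$logLik < ll - 1e-10 * max(1, abs(ll)))
      warning("observed-data log-likelihood decreased at iteration ", it)
    trace <- c(trace, es$logLik)
    if (is.finite(ll) &&
        abs(es$logLik - ll) < control$tol * max(1, abs(ll))) {
      ll <- es$logLik
      break
    }
    ll <- es$logLik
    ms <- mStepJointDM(data, r, alphaRna, alphaAdt,
                       maxInner = control$maxInner)
    alphaRna <- ms$alphaRna
    alphaAdt <- ms$alphaAdt
    pi <- ms$pi
  }

  labels <- max.col(r, ties.method = "first")
  pars <- DMParams(alphaRna, alphaAdt, z = labels,
                   b = rep(1, ncol(data)), sigmaB2 = 1)
  res <- new("DMClusterResult", labels = as.integer(labels), posterior = r,
             selectedChain = 1L, logPostTrace = trace, paramsHat = pars,
             method = "jointdm")
  attr(res, "pi") <- pi
  res
}
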