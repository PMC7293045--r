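# Independent oracles and tiny fixtures shared across tests. Everything
# here is deliberately written from first principles (loops, closed forms,
# base-R distribution functions) so it exercises none of the package's
# computational paths.

# Beta-binomial log-pmf via lchoose/lbeta: the m = 2 Dirichlet-multinomial
# marginal in closed form.
betaBinomLogPmf <- function(x, n, a, b) {
  lchoose(n, x) + lbeta(x + a, n - x + b) - lbeta(a, b)
}

# All compositions of total Tt into m non-negative parts (rows).
compositions <- function(m, Tt) {
  if (m == 1L) return(matrix(Tt, 1L, 1L))
  do.call(rbind, lapply(0:Tt, function(x1) {
    cbind(x1, compositions(m - 1L, Tt - x1))
  }))
}

# Complete log-posterior of the random-effects model re-derived with
# explicit per-cell loops (no shared code with the package internals).
refCompleteLogPost <- function(data, params) {
  X1 <- rnaCounts(data); X2 <- adtCounts(data)
  z <- params@z; b <- params@b; s2 <- params@sigmaB2
  total <- 0
  for (j in seq_along(z)) {
    for (src in 1:2) {
      X <- if (src == 1) X1 else X2
      A <- if (src == 1) params@alphaRna else params@alphaAdt
      x <- X[, j]; a <- A[z[j], ] * b[j]
      Tt <- sum(x)
      total <- total + lgamma(Tt + 1) - sum(lgamma(x + 1)) +
        sum(lgamma(x + a)) - sum(lgamma(a)) +
        lgamma(sum(a)) - lgamma(Tt + sum(a))
    }
    total <- total - log(b[j]) - log(b[j])^2 / (2 * s2) - 0.5 * log(s2)
  }
  total
}

# Brute-force pair-counting adjusted Rand index over all n-choose-2 pairs.
refARI <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]; sb <- b[i] == b[j]
      if (sa && sb) n11 <- n11 + 1
      else if (!sa && !sb) n00 <- n00 + 1
      else if (sa) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
  }
  np <- choose(n, 2)
  index <- n11
  expected <- (n11 + n10) * (n11 + n01) / np
  maxIndex <- ((n11 + n10) + (n11 + n01)) / 2
  if (abs(maxIndex - expected) < 1e-14) return(1)
  (index - expected) / (maxIndex - expected)
}

# Adjusted mutual information with the expected MI accumulated from
# dhyper() directly (hypergeometric fixed-margins model).
refAMI <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  ai <- rowSums(tab); bj <- colSums(tab)
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  Ha <- H(ai / n); Hb <- H(bj / n)
  MI <- 0
  for (i in seq_along(ai)) for (j in seq_along(bj)) {
    nij <- tab[i, j]
    if (nij > 0) MI <- MI + nij / n * log(n * nij / (ai[i] * bj[j]))
  }
  EMI <- 0
  for (i in seq_along(ai)) for (j in seq_along(bj)) {
    for (nij in max(1, ai[i] + bj[j] - n):min(ai[i], bj[j])) {
      if (nij < 1) next
      w <- dhyper(nij, ai[i], n - ai[i], bj[j])
      EMI <- EMI + w * nij / n * log(n * nij / (ai[i] * bj[j]))
    }
  }
  denom <- (Ha + Hb) / 2 - EMI
  if (abs(denom) < 1e-12) return(0)
  as.numeric((MI - EMI) / denom)
}

# Tiny deterministic paired fixture: C cells, small counts, no randomness.
makeToyPaired <- function() {
  rna <- matrix(c(5, 0, 2,
                  1, 3, 0,
                  0, 2, 4), nrow = 3, byrow = TRUE,
                dimnames = list(paste0("g", 1:3), paste0("c", 1:3)))
  adt <- matrix(c(10, 2, 7,
                  1, 8, 3), nrow = 2, byrow = TRUE,
                dimnames = list(paste0("m", 1:2), paste0("c", 1:3)))
  PairedCounts(rna, adt)
}

makeToyParams <- function(K = 2) {
  DMParams(alphaRna = matrix(c(2, 1, 0.5, 0.5, 1, 2), K, 3, byrow = TRUE),
           alphaAdt = matrix(c(3, 1, 1, 3), K, 2, byrow = TRUE),
           z = c(1L, 2L, 1L), b = c(1, 0.8, 1.3), sigmaB2 = 0.5)
}

# Small strong-signal simulation used by several behavioral tests.
quickSim <- function(K = 2, n = 40, G = 30, D = 8, sigmaB = 0.5, seed = 1) {
  simulateREDM(simConfig(K = K, cellsPerCluster = n, G = G, D = D,
                         sigmaB = sigmaB, seed = seed))
}
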