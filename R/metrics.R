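.contingency <- function(a, b) {
  if (length(a) != length(b))
    stop("label vectors must have the same length")
  if (length(a) < 2L) stop("at least two observations are required")
  table(factor(a), factor(b))
}

#' Adjusted Rand index
#'
#' Chance-adjusted pair-counting agreement between two labelings,
#' `ARI = (Index - Expected) / (Max - Expected)` computed from the label
#' contingency table. 1 means identical partitions (up to label
#' permutation), 0 the expectation under random labellings, negative values
#' worse than chance. Both degenerate partitions being trivial in the same
#' way (denominator zero) returns 1.
#'
#' @param labelsA,labelsB label vectors of equal length (any atomic type).
#' @return A scalar in `[-1, 1]`.
#' @examples
#' adjustedRandIndex(c(0, 0, 1, 1), c(0, 1, 0, 1))  # -0.5
#' @export
adjustedRandIndex <- function(labelsA, labelsB) {
  tab <- .contingency(labelsA, labelsB)
  n <- sum(tab)
  sumij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  expected <- ai * bj / choose(n, 2)
  maxIndex <- (ai + bj) / 2
  if (abs(maxIndex - expected) < .Machine$double.eps * max(1, maxIndex))
    return(1)
  (sumij - expected) / (maxIndex - expected)
}

#' Adjusted mutual information
#'
#' Chance-adjusted information-theoretic agreement between two labelings,
#' `AMI = (MI - E[MI]) / (mean(H_A, H_B) - E[MI])`, with the expected
#' mutual information taken over the hypergeometric (fixed-margins) model
#' and the arithmetic mean of the two entropies as normalizer. Natural
#' logarithms throughout; symmetric in its arguments. Degenerate 0/0 cases
#' (e.g. one argument a single cluster) return 0.
#'
#' @inheritParams adjustedRandIndex
#' @return A scalar no larger than 1.
#' @export
adjustedMutualInfo <- function(labelsA, labelsB) {
  tab <- .contingency(labelsA, labelsB)
  n <- sum(tab)
  a <- rowSums(tab)
  b <- colSums(tab)
  pa <- a / n
  pb <- b / n
  Ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  Hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  p <- tab / n
  pe <- outer(pa, pb)
  nz <- p > 0
  MI <- sum(p[nz] * log(p[nz] / pe[nz]))

  # E[MI] under random labellings with the observed margins: sum over all
  # admissible cell counts nij with hypergeometric weights, written with
  # log-factorials to stay stable at n in the thousands.
  EMI <- 0
  lf <- lfactorial
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      lo <- max(1, a[i] + b[j] - n)
      hi <- min(a[i], b[j])
      if (hi < lo) next
      nij <- lo:hi
      logw <- lf(a[i]) + lf(b[j]) + lf(n - a[i]) + lf(n - b[j]) - lf(n) -
        lf(nij) - lf(a[i] - nij) - lf(b[j] - nij) -
        lf(n - a[i] - b[j] + nij)
      EMI <- EMI + sum(nij / n * log(n * nij / (a[i] * b[j])) * exp(logw))
    }
  }
  denom <- (Ha + Hb) / 2 - EMI
  if (abs(denom) < 1e-12) return(0)
  (MI - EMI) / denom
}
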