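# Normalize columns to proportions, scale to 1e4 and log1p — the usual
# stabilization of Euclidean distances on counts before K-means.
.logNormalize <- function(X) {
  tot <- colSums(X)
  tot[tot == 0] <- 1
  log1p(sweep(X, 2L, tot, "/") * 1e4)
}

#' K-means labels for one count matrix
#'
#' Runs K-means on the log1p-transformed, per-cell total-normalized columns
#' of a features x cells count matrix. Deterministic given `seed`.
#'
#' @param X features x cells count matrix.
#' @param K number of clusters, at most the number of cells.
#' @param seed integer seed.
#' @param nstart number of K-means restarts.
#' @return Integer label vector of length `ncol(X)` with values in `1..K`.
#' @export
kmeansLabels <- function(X, K, seed = 1L, nstart = 10L) {
  K <- as.integer(K)
  if (K < 1L || K > ncol(X))
    stop("K must lie between 1 and the number of cells")
  if (K == 1L) return(rep(1L, ncol(X)))
  Y <- t(.logNormalize(as.matrix(X)))
  set.seed(as.integer(seed))
  km <- suppressWarnings(stats::kmeans(Y, centers = K, nstart = nstart,
                                       iter.max = 100L))
  as.integer(km$cluster)
}

#' Moment estimation of Dirichlet parameters per cluster
#'
#' Method-of-moments initial values for the Dirichlet parameter rows, in
#' the style of Ronning's estimator: within each cluster, each cell's
#' proportion vector `p_j = x_j / T_j` is computed, the mean proportion
#' vector is scaled by a precision estimated from the first coordinate's
#' moment identity `s = pbar_1 (1 - pbar_1) / var(p_1) - 1`. When the
#' moment precision is undefined or non-positive (degenerate variance, a
#' single cell, or an uninformative first coordinate) the conservative
#' fallback `s = 1 / min positive(pbar)` is used. All entries are floored
#' at 1e-6.
#'
#' @param X features x cells count matrix.
#' @param labels integer cluster labels of the cells, in `1..K`.
#' @param K number of clusters; every cluster must be non-empty.
#' @return K x features matrix of strictly positive parameters.
#' @export
ronningAlpha <- function(X, labels, K) {
  X <- as.matrix(X)
  K <- as.integer(K)
  sizes <- tabulate(labels, K)
  if (any(sizes == 0L))
    stop("cluster ", which(sizes == 0L)[1L], " is empty")
  alpha <- matrix(NA_real_, K, nrow(X))
  colnames(alpha) <- rownames(X)
  P <- sweep(X, 2L, pmax(colSums(X), 1), "/")
  for (k in seq_len(K)) {
    Pk <- P[, labels == k, drop = FALSE]
    pbar <- rowMeans(Pk)
    s <- NA_real_
    if (ncol(Pk) >= 2L) {
      v1 <- stats::var(Pk[1L, ])
      p1 <- pbar[1L]
      if (is.finite(v1) && v1 > 1e-12 && p1 > 0 && p1 < 1)
        s <- p1 * (1 - p1) / v1 - 1
    }
    if (!is.finite(s) || s <= 0)
      s <- 1 / min(pbar[pbar > 0])
    alpha[k, ] <- pmax(pbar * s, 1e-6)
  }
  alpha
}

# Map labels `from` onto the label space of `to` by maximizing contingency
# overlap: exact over all permutations for K <= 8, greedy otherwise.
.matchClusterLabels <- function(from, to, K) {
  tab <- matrix(0, K, K)
  tt <- table(factor(from, levels = seq_len(K)),
              factor(to, levels = seq_len(K)))
  tab[seq_len(K), seq_len(K)] <- tt
  if (K <= 8L) {
    perms <- .permutations(K)
    overlaps <- apply(perms, 1L, function(p) sum(tab[cbind(seq_len(K), p)]))
    best <- perms[which.max(overlaps), ]
  } else {
    best <- integer(K)
    used <- logical(K)
    for (k in order(-apply(tab, 1L, max))) {
      cand <- order(-tab[k, ])
      best[k] <- cand[!used[cand]][1L]
      used[best[k]] <- TRUE
    }
  }
  unname(best[from])
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Initial parameter state from per-source K-means
#'
#' Builds the initial state for either fitting routine: K-means is run on
#' each source separately; the RNA label set is mapped onto the ADT label
#' space by maximizing contingency overlap (exact assignment for K <= 8);
#' the ADT-derived labels (the lower-dimensional, typically more
#' discriminative source) become the initial `z`; and each source's
#' Dirichlet rows are estimated from its own counts under this common
#' labeling by [ronningAlpha()]. Random effects start at 1 and sigma_b^2
#' at 1.
#'
#' @inheritParams runREDM
#' @param seed integer seed (used for both K-means runs).
#' @return A [DMParams-class] object.
#' @export
initialModelParams <- function(data, K, seed = 1L) {
  K <- as.integer(K)
  zRna <- kmeansLabels(data@rnaCounts, K, seed = seed)
  zAdt <- kmeansLabels(data@adtCounts, K, seed = seed + 1L)
  z <- if (K == 1L) zAdt else .matchClusterLabels(zAdt, zRna, K)
  # remap can leave a cluster empty only if K-means did; it cannot, but a
  # defensive reseat keeps ronningAlpha's precondition satisfied
  sizes <- tabulate(z, K)
  if (any(sizes == 0L)) {
    for (k in which(sizes == 0L)) {
      donor <- which.max(tabulate(z, K))
      z[which(z == donor)[1L]] <- k
    }
  }
  DMParams(alphaRna = ronningAlpha(data@rnaCounts, z, K),
           alphaAdt = ronningAlpha(data@adtCounts, z, K),
           z = z, b = rep(1, ncol(data)), sigmaB2 = 1)
}

#' Choose the number of clusters by AIC or BIC
#'
#' Fits the EM independence model for each candidate `K` and scores the
#' maximized observed-data log-likelihood with AIC = -2 l + 2 nu or
#' BIC = -2 l + nu log C, where `nu = K (G + D) + (K - 1)` counts the free
#' Dirichlet parameters and mixing proportions. Returns the argmin.
#'
#' @inheritParams runJointDM
#' @param kGrid integer vector of candidate cluster numbers, each at most
#'   the number of cells.
#' @param criterion `"BIC"` (default) or `"AIC"`.
#' @return A list with `K` (the chosen value) and `table` (a data frame
#'   with columns `K`, `logLik`, `nu`, `AIC`, `BIC`).
#' @export
selectK <- function(data, kGrid, control = emControl(),
                    criterion = c("BIC", "AIC")) {
  criterion <- match.arg(criterion)
  kGrid <- as.integer(kGrid)
  if (any(kGrid < 1L) || any(kGrid > ncol(data)))
    stop("all grid values must lie between 1 and the number of cells")
  C <- ncol(data)
  G <- nrow(data@rnaCounts)
  D <- nrow(data@adtCounts)
  rows <- lapply(kGrid, function(K) {
    fit <- runJointDM(data, K, control)
    ll <- fit@logPostTrace[length(fit@logPostTrace)]
    nu <- K * (G + D) + (K - 1L)
    data.frame(K = K, logLik = ll, nu = nu,
               AIC = -2 * ll + 2 * nu, BIC = -2 * ll + nu * log(C))
  })
  tab <- do.call(rbind, rows)
  list(K = tab$K[which.min(tab[[criterion]])], table = tab)
}
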