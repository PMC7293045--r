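# Truncated-normal draws by inverse-CDF (exact, vectorized): lower
# truncation only, rounded to nearest integer and floored at the bound.
.rTruncTotals <- function(n, spec) {
  lo <- stats::pnorm(spec[["lower"]], spec[["mean"]], spec[["sd"]])
  u <- stats::runif(n, lo, 1)
  pmax(round(stats::qnorm(u, spec[["mean"]], spec[["sd"]])),
       ceiling(spec[["lower"]]))
}

.rDirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Simulation configuration for the generative model
#'
#' Bundles and validates everything the generative recipe needs. The
#' default library-size specifications (RNA: truncated normal with mean
#' 2500, sd 800, lower bound 500; ADT: mean 5000, sd 1500, lower bound
#' 100) are synthetic stand-ins chosen to resemble typical CITE-seq
#' depths; they are configuration defaults, not estimates from any real
#' dataset.
#'
#' When `alphaRna`/`alphaAdt` are not supplied they are built as a shared
#' positive baseline plus per-cluster marker blocks whose fold-elevation is
#' set by `signal` (`"strong"`: 8-fold on RNA and ADT; `"weak"`: 2-fold on
#' RNA, 1.5-fold on ADT), reproducibly from `seed`.
#'
#' @param K number of clusters.
#' @param cellsPerCluster integer vector of length K (a scalar is
#'   recycled).
#' @param G,D numbers of genes and ADT markers.
#' @param sigmaB standard deviation of `log(b)`; 0 disables the random
#'   effects.
#' @param alphaRna,alphaAdt optional K x G / K x D positive matrices.
#' @param signalRna,signalAdt `"strong"` or `"weak"` marker elevation used
#'   when the alpha matrices are auto-built.
#' @param rnaTotal,adtTotal named vectors `c(mean=, sd=, lower=)` of the
#'   truncated-normal library-size distributions.
#' @param seed integer seed.
#' @return A validated list of class `"redm_sim_config"`.
#' @export
simConfig <- function(K = 3L, cellsPerCluster = 100L, G = 60L, D = 10L,
                      sigmaB = 0.5, alphaRna = NULL, alphaAdt = NULL,
                      signalRna = c("strong", "weak"),
                      signalAdt = c("strong", "weak"),
                      rnaTotal = c(mean = 2500, sd = 800, lower = 500),
                      adtTotal = c(mean = 5000, sd = 1500, lower = 100),
                      seed = 1L) {
  signalRna <- match.arg(signalRna)
  signalAdt <- match.arg(signalAdt)
  K <- as.integer(K)
  G <- as.integer(G)
  D <- as.integer(D)
  if (K < 1L || G < 1L || D < 1L) stop("K, G and D must be at least 1")
  if (length(cellsPerCluster) == 1L)
    cellsPerCluster <- rep(as.integer(cellsPerCluster), K)
  cellsPerCluster <- as.integer(cellsPerCluster)
  if (length(cellsPerCluster) != K || any(cellsPerCluster < 1L))
    stop("cellsPerCluster must give a positive size for each of K clusters")
  if (!is.finite(sigmaB) || sigmaB < 0) stop("sigmaB must be non-negative")
  for (spec in list(rnaTotal, adtTotal))
    if (any(spec[c("mean", "sd")] <= 0) || spec[["lower"]] < 0)
      stop("library-size specs need positive mean and sd and lower >= 0")
  if (is.null(alphaRna))
    alphaRna <- .markerAlpha(K, G, fold = if (signalRna == "strong") 8 else 2,
                             baseRange = c(0.5, 1.5),
                             seed = as.integer(seed) + 101L)
  if (is.null(alphaAdt))
    alphaAdt <- .markerAlpha(K, D,
                             fold = if (signalAdt == "strong") 8 else 1.5,
                             baseRange = c(2, 6),
                             seed = as.integer(seed) + 202L)
  alphaRna <- as.matrix(alphaRna)
  alphaAdt <- as.matrix(alphaAdt)
  if (!all(dim(alphaRna) == c(K, G)) || any(alphaRna <= 0))
    stop("alphaRna must be a positive K x G matrix")
  if (!all(dim(alphaAdt) == c(K, D)) || any(alphaAdt <= 0))
    stop("alphaAdt must be a positive K x D matrix")
  structure(list(K = K, cellsPerCluster = cellsPerCluster, G = G, D = D,
                 sigmaB = sigmaB, alphaRna = alphaRna, alphaAdt = alphaAdt,
                 rnaTotal = rnaTotal, adtTotal = adtTotal,
                 seed = as.integer(seed)),
            class = "redm_sim_config")
}

# Shared baseline + per-cluster marker blocks: features are split into K
# contiguous blocks and block k is elevated `fold`-fold in cluster k.
.markerAlpha <- function(K, F, fold, baseRange, seed) {
  set.seed(seed)
  base <- stats::runif(F, baseRange[1L], baseRange[2L])
  block <- max(1L, F %/% K)
  alpha <- matrix(rep(base, each = K), K, F, byrow = FALSE)
  for (k in seq_len(K)) {
    idx <- seq.int((k - 1L) * block + 1L, min(k * block, F))
    alpha[k, idx] <- alpha[k, idx] * fold
  }
  alpha
}

#' Simulate paired counts from the random-effects generative model
#'
#' The generative recipe of the joint model itself: for each cell `j` of
#' true cluster `k`, draw `b_j ~ LogNormal(0, sigmaB^2)`; scale both
#' cluster parameter rows by `b_j`; draw the latent proportion vectors
#' `p_j ~ Dirichlet(alpha_k * b_j)` per source; draw library sizes from
#' the rounded truncated normals; and draw the count columns
#' `x_j ~ Multinomial(T_j, p_j)`. Column sums equal the drawn totals
#' exactly; everything is reproducible from `config$seed`.
#'
#' @param config a [simConfig()] list.
#' @return A list with `counts` (a [PairedCounts-class]) and `truth` (a
#'   list with `zTrue`, `bTrue`, `paramsTrue` as [DMParams-class], and the
#'   drawn totals `rnaTotals`, `adtTotals`).
#' @export
simulateREDM <- function(config) {
  if (!inherits(config, "redm_sim_config"))
    config <- do.call(simConfig, config)
  set.seed(config$seed)
  K <- config$K
  C <- sum(config$cellsPerCluster)
  z <- rep(seq_len(K), config$cellsPerCluster)
  b <- if (config$sigmaB > 0) exp(stats::rnorm(C, 0, config$sigmaB))
       else rep(1, C)
  T1 <- .rTruncTotals(C, config$rnaTotal)
  T2 <- .rTruncTotals(C, config$adtTotal)
  X1 <- matrix(0, config$G, C)
  X2 <- matrix(0, config$D, C)
  for (j in seq_len(C)) {
    p1 <- .rDirichlet(config$alphaRna[z[j], ] * b[j])
    p2 <- .rDirichlet(config$alphaAdt[z[j], ] * b[j])
    X1[, j] <- stats::rmultinom(1L, T1[j], p1)
    X2[, j] <- stats::rmultinom(1L, T2[j], p2)
  }
  counts <- PairedCounts(X1, X2)
  truth <- list(zTrue = z, bTrue = b,
                paramsTrue = DMParams(config$alphaRna, config$alphaAdt,
                                      z = z, b = b,
                                      sigmaB2 = max(config$sigmaB^2, 1e-8)),
                rnaTotals = T1, adtTotals = T2)
  list(counts = counts, truth = truth)
}

#' Simulate paired counts under gamma-Poisson misspecification
#'
#' A deliberately misspecified generator for robustness studies: counts
#' are negative-binomial (gamma-Poisson), not Dirichlet-multinomial.
#' Baseline feature means are log-normal; within each cluster a `deProb`
#' fraction of features is differentially expressed, its mean multiplied
#' or divided by `deFold`; per-cell means are rescaled to truncated-normal
#' library sizes; counts are `NB(mu, size = dispersion)`, approaching
#' Poisson as `dispersion` grows. ADT is generated the same way with `D`
#' features, larger totals and its own dispersion.
#'
#' @param K,cellsPerCluster,G,D,rnaTotal,adtTotal,seed as [simConfig()].
#' @param deProb probability in `[0, 1]` that a feature is differentially
#'   expressed in a given cluster.
#' @param deFold fold change applied to differentially expressed features
#'   (direction chosen at random per feature).
#' @param dispersionRna,dispersionAdt NB size parameters.
#' @return As [simulateREDM()]; `truth$paramsTrue` is `NULL` (the model
#'   does not generate the data) and the per-cluster DE feature indicators
#'   are returned as `truth$deGenes` / `truth$deMarkers` (K x features
#'   logical matrices).
#' @export
simulateGammaPoisson <- function(K = 3L, cellsPerCluster = 100L, G = 60L,
                                 D = 10L, deProb = 0.5, deFold = 4,
                                 dispersionRna = 2, dispersionAdt = 5,
                                 rnaTotal = c(mean = 2500, sd = 800,
                                              lower = 500),
                                 adtTotal = c(mean = 5000, sd = 1500,
                                              lower = 100),
                                 seed = 1L) {
  if (!is.finite(deProb) || deProb < 0 || deProb > 1)
    stop("deProb must lie in [0, 1]")
  if (deFold < 1) stop("deFold must be at least 1")
  K <- as.integer(K)
  if (length(cellsPerCluster) == 1L)
    cellsPerCluster <- rep(as.integer(cellsPerCluster), K)
  set.seed(as.integer(seed))
  C <- sum(cellsPerCluster)
  z <- rep(seq_len(K), cellsPerCluster)

  genSource <- function(F, totalSpec, dispersion) {
    base <- exp(stats::rnorm(F, 0, 0.5))
    de <- matrix(stats::runif(K * F) < deProb, K, F)
    dirUp <- matrix(stats::runif(K * F) < 0.5, K, F)
    fac <- matrix(1, K, F)
    fac[de & dirUp] <- deFold
    fac[de & !dirUp] <- 1 / deFold
    means <- sweep(fac, 2L, base, "*")
    Tt <- .rTruncTotals(C, totalSpec)
    X <- matrix(0, F, C)
    for (j in seq_len(C)) {
      mu <- means[z[j], ]
      mu <- mu / sum(mu) * Tt[j]
      X[, j] <- stats::rnbinom(F, size = dispersion, mu = mu)
    }
    list(X = X, de = de)
  }
  rna <- genSource(as.integer(G), rnaTotal, dispersionRna)
  adt <- genSource(as.integer(D), adtTotal, dispersionAdt)
  counts <- PairedCounts(rna$X, adt$X)
  list(counts = counts,
       truth = list(zTrue = z, bTrue = rep(1, C), paramsTrue = NULL,
                    deGenes = rna$de, deMarkers = adt$de))
}

#' Preset simulation scenarios
#'
#' A named list of [simConfig()] presets spanning the study dimensions:
#' among-cell variability `sigmaB` in {0, 0.5, 1, 2}, the four
#' signal-strength combinations of the two sources (both strong, ADT weak /
#' RNA strong, ADT strong / RNA weak, both weak), cells per cluster in
#' {50, 100, 200} and cluster numbers K in {3, 5, 8}. The base scenario is
#' `sigma0.5_bothS_n100_K3`; each preset varies one dimension.
#'
#' @param seed integer seed shared by the presets.
#' @return Named list of `"redm_sim_config"` objects.
#' @export
defaultScenarios <- function(seed = 1L) {
  out <- list()
  for (s in c(0, 0.5, 1, 2))
    out[[sprintf("sigma%s_bothS_n100_K3", s)]] <-
      simConfig(K = 3, cellsPerCluster = 100, sigmaB = s, seed = seed)
  sigs <- list(bothS = c("strong", "strong"),
               adtW_rnaS = c("strong", "weak"),
               adtS_rnaW = c("weak", "strong"),
               bothW = c("weak", "weak"))
  for (nm in names(sigs))
    out[[sprintf("sigma0.5_%s_n100_K3", nm)]] <-
      simConfig(K = 3, cellsPerCluster = 100, sigmaB = 0.5,
                signalRna = sigs[[nm]][1L], signalAdt = sigs[[nm]][2L],
                seed = seed)
  for (n in c(50, 100, 200))
    out[[sprintf("sigma0.5_bothS_n%d_K3", n)]] <-
      simConfig(K = 3, cellsPerCluster = n, sigmaB = 0.5, seed = seed)
  for (K in c(3, 5, 8))
    out[[sprintf("sigma0.5_bothS_n100_K%d", K)]] <-
      simConfig(K = K, cellsPerCluster = 100, sigmaB = 0.5, seed = seed)
  out[!duplicated(names(out))]
}
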