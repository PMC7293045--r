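#' Dirichlet-multinomial log probability mass
#'
#' Exact log-pmf of the Dirichlet-multinomial (multivariate Polya)
#' distribution, the marginal of a multinomial whose probability vector has
#' been integrated over a `Dirichlet(alpha)` prior:
#' \deqn{\log P(x \mid \alpha) = \log\frac{T!}{\prod_i x_i!}
#'   + \sum_i [\log\Gamma(x_i + \alpha_i) - \log\Gamma(\alpha_i)]
#'   + \log\Gamma(|\alpha|) - \log\Gamma(T + |\alpha|)}
#' with \eqn{T = \sum_i x_i} and \eqn{|\alpha| = \sum_i \alpha_i}. The
#' multinomial coefficient is included, so `exp(dmLogPmf(...))` sums to one
#' over all compositions of a fixed total. Everything is computed in log
#' space via `lgamma`, so totals in the thousands are safe.
#'
#' @param x non-negative integer count vector.
#' @param alpha strictly positive parameter vector, same length as `x`.
#' @return A finite scalar, the log probability of `x`.
#' @examples
#' dmLogPmf(c(1, 1), c(1, 1))  # log(1/3): uniform beta-binomial
#' @export
dmLogPmf <- function(x, alpha) {
  if (length(x) != length(alpha))
    stop("x and alpha must have the same length")
  if (any(!is.finite(alpha)) || any(alpha <= 0))
    stop("alpha entries must be finite and strictly positive")
  if (any(!is.finite(x)) || any(x < 0) || any(x != round(x)))
    stop("x entries must be finite non-negative integers")
  T <- sum(x)
  lgamma(T + 1) - sum(lgamma(x + 1)) +
    sum(lgamma(x + alpha) - lgamma(alpha)) +
    lgamma(sum(alpha)) - lgamma(T + sum(alpha))
}

# Per-cell log multinomial coefficients log[T_j!/(prod_i x_ij!)] for a
# features x cells matrix; constant in all model parameters.
.dmCoef <- function(X) {
  lgamma(colSums(X) + 1) - colSums(lgamma(X + 1))
}

.checkDims <- function(data, params) {
  if (ncol(params@alphaRna) != nrow(data@rnaCounts))
    stop("alphaRna has ", ncol(params@alphaRna), " genes but data has ",
         nrow(data@rnaCounts))
  if (ncol(params@alphaAdt) != nrow(data@adtCounts))
    stop("alphaAdt has ", ncol(params@alphaAdt), " markers but data has ",
         nrow(data@adtCounts))
  if (length(params@z) != ncol(data@rnaCounts))
    stop("params describe ", length(params@z), " cells but data has ",
         ncol(data@rnaCounts))
  invisible(TRUE)
}

#' Per-cell, per-cluster Dirichlet-multinomial log-likelihood matrix
#'
#' For every cell `j` and cluster `k`, the sum of the two source-specific
#' DM log-densities evaluated at the cell-scaled parameters
#' `alphaRna[k, ] * b[j]` and `alphaAdt[k, ] * b[j]`. Multinomial
#' coefficients are included when `includeCoef = TRUE`.
#'
#' @param data a [PairedCounts-class] object.
#' @param params a [DMParams-class] object.
#' @param includeCoef include the parameter-free multinomial coefficients.
#' @return A C x K matrix of finite log-likelihood values.
#' @export
dmLogLikMatrix <- function(data, params, includeCoef = TRUE) {
  .checkDims(data, params)
  W <- cc_dm_loglik_mat(data@rnaCounts, params@alphaRna, params@b) +
    cc_dm_loglik_mat(data@adtCounts, params@alphaAdt, params@b)
  if (includeCoef)
    W <- W + .dmCoef(data@rnaCounts) + .dmCoef(data@adtCounts)
  W
}

#' Joint log-likelihood under the independence model
#'
#' The joint log-likelihood of both sources assuming full independence
#' between RNA and ADT given the cluster labels (no cell random effects):
#' the sum over cells of the two DM log-densities at each cell's assigned
#' cluster row.
#'
#' @inheritParams dmLogLikMatrix
#' @return A finite scalar.
#' @export
logLikIndependent <- function(data, params) {
  .checkDims(data, params)
  C <- length(params@z)
  one <- rep(1, C)
  W <- cc_dm_loglik_mat(data@rnaCounts, params@alphaRna, one) +
    cc_dm_loglik_mat(data@adtCounts, params@alphaAdt, one)
  sum(W[cbind(seq_len(C), params@z)]) +
    sum(.dmCoef(data@rnaCounts)) + sum(.dmCoef(data@adtCounts))
}

#' Complete log-posterior of the random-effects model
#'
#' The complete-data log-posterior of the random-effects model: the two DM
#' log-density sums with each cluster row scaled by the cell random effect
#' `b[j]`, plus the log-normal random-effect prior
#' \eqn{\sum_j [-\log b_j - (\log b_j)^2/(2\sigma_b^2)]} and the variance
#' normalization \eqn{\sum_j(-\frac{1}{2}\log\sigma_b^2)}. Multinomial
#' coefficients are included (they are constant in all parameters).
#'
#' With all `b[j] = 1` the DM part equals that of [logLikIndependent()] and
#' the prior part reduces to `-C/2 * log(sigmaB2)`.
#'
#' @inheritParams dmLogLikMatrix
#' @return A finite scalar.
#' @export
completeLogPosterior <- function(data, params) {
  .checkDims(data, params)
  if (any(params@b <= 0)) stop("b entries must be strictly positive")
  if (params@sigmaB2 <= 0) stop("sigmaB2 must be positive")
  C <- length(params@z)
  W <- dmLogLikMatrix(data, params, includeCoef = TRUE)
  lb <- log(params@b)
  sum(W[cbind(seq_len(C), params@z)]) +
    sum(-lb - lb^2 / (2 * params@sigmaB2)) -
    C / 2 * log(params@sigmaB2)
}

#' Gibbs full-conditional log-weights of one cell's cluster label
#'
#' Unnormalized log-probabilities of the full conditional of `z[j]` under a
#' uniform categorical prior over clusters: entry `k` is the sum of the two
#' DM log-densities of cell `j` at `alpha[k, ] * b[j]` (multinomial
#' coefficients omitted; they cancel in the normalization). Exponentiating
#' and normalizing yields the Gibbs sampling probabilities.
#'
#' @inheritParams dmLogLikMatrix
#' @param j cell index in `1..C`.
#' @return A finite numeric vector of length K.
#' @export
cellClusterLogWeights <- function(data, params, j) {
  .checkDims(data, params)
  if (length(j) != 1L || j < 1 || j > ncol(data@rnaCounts))
    stop("j must be a single cell index in 1..C")
  cell <- data[, j]
  p1 <- params@alphaRna * params@b[j]
  p2 <- params@alphaAdt * params@b[j]
  drop(cc_dm_loglik_mat(cell@rnaCounts, p1, 1) +
         cc_dm_loglik_mat(cell@adtCounts, p2, 1))
}

# Row-wise softmax with max subtraction; rows of the result sum to 1.
.softmaxRows <- function(W) {
  M <- W - apply(W, 1L, max)
  P <- exp(M)
  P / rowSums(P)
}
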