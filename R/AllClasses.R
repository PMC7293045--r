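#' @import methods
NULL

#' Paired RNA/ADT count matrices for one set of cells
#'
#' Container for the two aligned count matrices produced by a CITE-seq
#' experiment: RNA UMI counts (genes x cells) and antibody-derived tag (ADT)
#' counts (protein markers x cells), over the same cells in the same order.
#' Both matrices follow the 10x convention of features in rows and cells in
#' columns.
#'
#' @slot rnaCounts numeric matrix of non-negative integers, genes x cells.
#' @slot adtCounts numeric matrix of non-negative integers, markers x cells.
#'
#' Gene, marker and cell identifiers are carried as the dimnames of the two
#' matrices; the column names must agree between the sources.
#'
#' @seealso [PairedCounts()] for the validating constructor,
#'   [rnaCounts()], [adtCounts()], [cellIds()] for accessors.
#' @export
setClass("PairedCounts",
         representation(rnaCounts = "matrix", adtCounts = "matrix"))

.validCountMatrix <- function(m, what) {
  if (!is.numeric(m)) return(sprintf("%s matrix must be numeric", what))
  if (nrow(m) < 1L || ncol(m) < 1L)
    return(sprintf("%s matrix must have at least one feature and one cell",
                   what))
  if (any(!is.finite(m))) return(sprintf("%s matrix has non-finite entries",
                                         what))
  if (any(m < 0)) return(sprintf("%s matrix has negative entries", what))
  if (any(m != round(m))) return(sprintf("%s matrix has non-integer entries",
                                         what))
  NULL
}

setValidity("PairedCounts", function(object) {
  msgs <- c(.validCountMatrix(object@rnaCounts, "RNA"),
            .validCountMatrix(object@adtCounts, "ADT"))
  if (ncol(object@rnaCounts) != ncol(object@adtCounts))
    msgs <- c(msgs, sprintf("RNA has %d cells but ADT has %d",
                            ncol(object@rnaCounts), ncol(object@adtCounts)))
  rn <- colnames(object@rnaCounts)
  an <- colnames(object@adtCounts)
  if (!is.null(rn) && !is.null(an) && !identical(rn, an))
    msgs <- c(msgs, "RNA and ADT cell identifiers disagree or are reordered")
  if (length(msgs)) msgs else TRUE
})

#' Parameters of the random-effects Dirichlet-multinomial mixture
#'
#' Holds one full parameter state of the joint model: the cluster-level
#' Dirichlet parameter blocks for the RNA and ADT sources, the cell-specific
#' positive random effects `b`, their log-normal variance `sigmaB2`, and the
#' current hard cluster labels `z`. The effective Dirichlet parameters of
#' cell `j` in cluster `k` are the rows `alphaRna[k, ] * b[j]` and
#' `alphaAdt[k, ] * b[j]`.
#'
#' @slot alphaRna K x G matrix of strictly positive reals.
#' @slot alphaAdt K x D matrix of strictly positive reals.
#' @slot b numeric vector of length C, strictly positive.
#' @slot sigmaB2 positive scalar, variance of `log(b)`.
#' @slot z integer vector of length C with values in `1..K`.
#'
#' @export
setClass("DMParams",
         representation(alphaRna = "matrix", alphaAdt = "matrix",
                        b = "numeric", sigmaB2 = "numeric", z = "integer"))

setValidity("DMParams", function(object) {
  msgs <- character()
  if (nrow(object@alphaRna) != nrow(object@alphaAdt))
    msgs <- c(msgs, "alphaRna and alphaAdt disagree on the number of clusters")
  if (any(!is.finite(object@alphaRna)) || any(object@alphaRna <= 0))
    msgs <- c(msgs, "alphaRna entries must be finite and strictly positive")
  if (any(!is.finite(object@alphaAdt)) || any(object@alphaAdt <= 0))
    msgs <- c(msgs, "alphaAdt entries must be finite and strictly positive")
  if (any(!is.finite(object@b)) || any(object@b <= 0))
    msgs <- c(msgs, "b entries must be finite and strictly positive")
  if (length(object@sigmaB2) != 1L || !is.finite(object@sigmaB2) ||
      object@sigmaB2 <= 0)
    msgs <- c(msgs, "sigmaB2 must be a positive scalar")
  if (length(object@z) != length(object@b))
    msgs <- c(msgs, "z and b must have one entry per cell")
  K <- nrow(object@alphaRna)
  if (length(object@z) && (min(object@z) < 1L || max(object@z) > K))
    msgs <- c(msgs, sprintf("z labels must lie in 1..%d", K))
  if (length(msgs)) msgs else TRUE
})

#' One MCMC chain trace
#'
#' Per-iteration record of a single Metropolis-within-Gibbs chain: the
#' sampled label vectors, the complete log-posterior, the sigma_b^2 draws,
#' running acceptance fractions for each Metropolis block, and the final
#' parameter state (with post-burn-in posterior-mean alpha blocks and b).
#'
#' @slot zSamples nIter x C integer matrix of sampled labels.
#' @slot logPost numeric vector of complete log-posterior values, one per
#'   sweep.
#' @slot sigmaB2Samples numeric vector of sigma_b^2 values, one per sweep.
#' @slot acceptRates named numeric vector: acceptance fractions for the
#'   `alpha_rna`, `alpha_adt` and `b` Metropolis blocks.
#' @slot finalParams a [DMParams-class] summary state.
#' @slot burnIn integer, number of initial sweeps treated as burn-in.
#'
#' @export
setClass("DMChain",
         representation(zSamples = "matrix", logPost = "numeric",
                        sigmaB2Samples = "numeric", acceptRates = "numeric",
                        finalParams = "DMParams", burnIn = "integer"))

setValidity("DMChain", function(object) {
  msgs <- character()
  if (length(object@logPost) != nrow(object@zSamples))
    msgs <- c(msgs, "logPost must have one entry per recorded sweep")
  if (any(!is.finite(object@logPost)))
    msgs <- c(msgs, "logPost contains non-finite values")
  if (any(object@acceptRates < 0 | object@acceptRates > 1))
    msgs <- c(msgs, "acceptance fractions must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Clustering result with soft assignments
#'
#' Final output of either fitting routine: hard labels, the C x K matrix of
#' per-cell posterior cluster probabilities (MCMC: post-burn-in assignment
#' frequencies from the selected chain; EM: final responsibilities), the
#' index of the selected chain, its log-posterior trace, and the parameter
#' estimate.
#'
#' @slot labels integer vector of length C with values in `1..K`.
#' @slot posterior C x K matrix; rows sum to one.
#' @slot selectedChain integer index of the maximum-likelihood chain (1 for
#'   EM fits).
#' @slot logPostTrace numeric trace of the selected chain (EM: observed-data
#'   log-likelihood per iteration).
#' @slot paramsHat a [DMParams-class] estimate.
#' @slot method character, `"redm"` or `"jointdm"`.
#'
#' @export
setClass("DMClusterResult",
         representation(labels = "integer", posterior = "matrix",
                        selectedChain = "integer", logPostTrace = "numeric",
                        paramsHat = "DMParams", method = "character"))

setValidity("DMClusterResult", function(object) {
  msgs <- character()
  if (length(object@labels) != nrow(object@posterior))
    msgs <- c(msgs, "labels must have one entry per posterior row")
  rs <- rowSums(object@posterior)
  if (length(rs) && any(abs(rs - 1) > 1e-9))
    msgs <- c(msgs, "posterior rows must sum to 1 (tolerance 1e-9)")
  am <- max.col(object@posterior, ties.method = "first")
  if (length(am) && !all(am == object@labels))
    msgs <- c(msgs, "labels must equal the row-wise argmax of posterior")
  if (length(msgs)) msgs else TRUE
})
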