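#' Construct a PairedCounts object
#'
#' Validates and bundles the two aligned count matrices of a CITE-seq
#' experiment. Cells must appear in the same order in both matrices; when
#' both carry column names these must agree. Missing dimnames are filled
#' with `gene1..G`, `adt1..D`, `cell1..C`.
#'
#' @param rna numeric matrix of non-negative integer UMI counts,
#'   genes x cells.
#' @param adt numeric matrix of non-negative integer ADT counts,
#'   markers x cells.
#' @return A [PairedCounts-class] object.
#' @examples
#' pc <- PairedCounts(rna = matrix(rpois(20, 5), 4, 5),
#'                    adt = matrix(rpois(10, 50), 2, 5))
#' pc
#' @export
PairedCounts <- function(rna, adt) {
  rna <- as.matrix(rna)
  adt <- as.matrix(adt)
  storage.mode(rna) <- "double"
  storage.mode(adt) <- "double"
  if (is.null(rownames(rna))) rownames(rna) <- paste0("gene", seq_len(nrow(rna)))
  if (is.null(rownames(adt))) rownames(adt) <- paste0("adt", seq_len(nrow(adt)))
  if (is.null(colnames(rna)) && is.null(colnames(adt))) {
    cn <- paste0("cell", seq_len(ncol(rna)))
    colnames(rna) <- cn
    if (ncol(adt) == ncol(rna)) colnames(adt) <- cn
  } else if (is.null(colnames(rna))) {
    colnames(rna) <- colnames(adt)
  } else if (is.null(colnames(adt))) {
    colnames(adt) <- colnames(rna)
  }
  new("PairedCounts", rnaCounts = rna, adtCounts = adt)
}

#' Accessors for PairedCounts
#'
#' @param x a [PairedCounts-class] object.
#' @return `rnaCounts` and `adtCounts` return the stored matrices;
#'   `cellIds`, `geneIds` and `markerIds` return identifier vectors;
#'   `ncol` returns the number of cells.
#' @name PairedCounts-accessors
NULL

#' @rdname PairedCounts-accessors
#' @export
setMethod("rnaCounts", "PairedCounts", function(x) x@rnaCounts)

#' @rdname PairedCounts-accessors
#' @export
setMethod("adtCounts", "PairedCounts", function(x) x@adtCounts)

#' @rdname PairedCounts-accessors
#' @export
setMethod("cellIds", "PairedCounts", function(x) colnames(x@rnaCounts))

#' @rdname PairedCounts-accessors
#' @export
setMethod("geneIds", "PairedCounts", function(x) rownames(x@rnaCounts))

#' @rdname PairedCounts-accessors
#' @export
setMethod("markerIds", "PairedCounts", function(x) rownames(x@adtCounts))

#' @rdname PairedCounts-accessors
#' @export
setMethod("ncol", "PairedCounts", function(x) ncol(x@rnaCounts))

#' @describeIn PairedCounts-accessors subset cells (and optionally features)
#'   jointly; `i` indexes genes, `j` cells, and the ADT matrix is subset on
#'   cells only.
#' @param i,j,...,drop see `[`; `i` selects genes, `j` selects cells.
#' @export
setMethod("[", "PairedCounts", function(x, i, j, ..., drop = FALSE) {
  rna <- x@rnaCounts
  adt <- x@adtCounts
  if (!missing(i)) rna <- rna[i, , drop = FALSE]
  if (!missing(j)) {
    rna <- rna[, j, drop = FALSE]
    adt <- adt[, j, drop = FALSE]
  }
  new("PairedCounts", rnaCounts = rna, adtCounts = adt)
})

setMethod("show", "PairedCounts", function(object) {
  cat("PairedCounts object\n")
  cat(sprintf("  RNA: %d genes x %d cells (median total %.0f)\n",
              nrow(object@rnaCounts), ncol(object@rnaCounts),
              stats::median(colSums(object@rnaCounts))))
  cat(sprintf("  ADT: %d markers x %d cells (median total %.0f)\n",
              nrow(object@adtCounts), ncol(object@adtCounts),
              stats::median(colSums(object@adtCounts))))
})

#' Construct a DMParams object
#'
#' @param alphaRna K x G matrix of positive Dirichlet parameters for RNA.
#' @param alphaAdt K x D matrix of positive Dirichlet parameters for ADT.
#' @param b positive cell random effects (default all 1).
#' @param sigmaB2 positive variance of `log(b)` (default 1).
#' @param z integer cluster labels in `1..K`.
#' @return A validated [DMParams-class] object.
#' @export
DMParams <- function(alphaRna, alphaAdt, z,
                     b = rep(1, length(z)), sigmaB2 = 1) {
  new("DMParams", alphaRna = as.matrix(alphaRna),
      alphaAdt = as.matrix(alphaAdt), b = as.numeric(b),
      sigmaB2 = as.numeric(sigmaB2), z = as.integer(z))
}

setMethod("show", "DMParams", function(object) {
  cat(sprintf("DMParams: K = %d, G = %d, D = %d, C = %d, sigmaB2 = %.4g\n",
              nrow(object@alphaRna), ncol(object@alphaRna),
              ncol(object@alphaAdt), length(object@z), object@sigmaB2))
})

setMethod("show", "DMChain", function(object) {
  cat(sprintf("DMChain: %d sweeps (%d burn-in), %d cells\n",
              nrow(object@zSamples), object@burnIn, ncol(object@zSamples)))
  cat(sprintf("  max log-posterior: %.2f\n", max(object@logPost)))
  cat("  acceptance:",
      paste(sprintf("%s = %.2f", names(object@acceptRates),
                    object@acceptRates), collapse = ", "), "\n")
})

#' Accessors for DMClusterResult
#'
#' @param x a [DMClusterResult-class] object.
#' @return `clusterLabels` returns the hard labels; `posteriorProbs` the
#'   C x K posterior-probability matrix.
#' @name DMClusterResult-accessors
NULL

#' @rdname DMClusterResult-accessors
#' @export
setMethod("clusterLabels", "DMClusterResult", function(x) x@labels)

#' @rdname DMClusterResult-accessors
#' @export
setMethod("posteriorProbs", "DMClusterResult", function(x) x@posterior)

setMethod("show", "DMClusterResult", function(object) {
  K <- ncol(object@posterior)
  cat(sprintf("DMClusterResult (%s): %d cells in %d clusters\n",
              object@method, length(object@labels), K))
  cat("  cluster sizes:",
      paste(tabulate(object@labels, K), collapse = ", "), "\n")
  if (length(object@logPostTrace))
    cat(sprintf("  final objective: %.2f (chain %d)\n",
                object@logPostTrace[length(object@logPostTrace)],
                object@selectedChain))
})
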