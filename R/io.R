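# Open a possibly gzip-compressed text file; R connections sniff the
# magic bytes, so gzfile() handles plain text too.
.openText <- function(path) gzfile(path, "rt")

.findTenxFile <- function(dir, stem) {
  for (cand in c(file.path(dir, stem), file.path(dir, paste0(stem, ".gz"))))
    if (file.exists(cand)) return(cand)
  stop("no ", stem, "[.gz] found in ", dir)
}

.readDenseCsv <- function(path) {
  con <- .openText(path)
  on.exit(close(con))
  df <- utils::read.csv(con, row.names = 1L, check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric entries in ", path)
  bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-count entry %s at row '%s', column '%s' of %s",
                 format(m[bad[1L, , drop = FALSE]]),
                 rownames(m)[bad[1L, 1L]], colnames(m)[bad[1L, 2L]],
                 basename(path)))
  m
}

# Read a 10x Matrix Market triplet directory; returns the dense count
# matrix with feature/barcode dimnames plus the feature-type column (third
# column of features.tsv when present).
.readTenx <- function(dir) {
  m <- as.matrix(Matrix::readMM(.findTenxFile(dir, "matrix.mtx")))
  fcon <- .openText(.findTenxFile(dir, "features.tsv"))
  feats <- utils::read.delim(fcon, header = FALSE,
                             stringsAsFactors = FALSE)
  close(fcon)
  bcon <- .openText(.findTenxFile(dir, "barcodes.tsv"))
  barcodes <- utils::read.delim(bcon, header = FALSE,
                                stringsAsFactors = FALSE)[[1L]]
  close(bcon)
  if (nrow(feats) != nrow(m))
    stop("features.tsv describes ", nrow(feats), " features but the matrix ",
         "has ", nrow(m), " rows")
  if (length(barcodes) != ncol(m))
    stop("barcodes.tsv lists ", length(barcodes), " cells but the matrix ",
         "has ", ncol(m), " columns")
  rownames(m) <- make.unique(feats[[min(2L, ncol(feats))]])
  colnames(m) <- barcodes
  if (any(m != round(m)) || any(m < 0))
    stop("matrix.mtx contains non-count entries")
  list(counts = m,
       type = if (ncol(feats) >= 3L) feats[[3L]] else
         rep("Gene Expression", nrow(m)))
}

#' Read paired RNA/ADT counts from disk
#'
#' Supports (a) a 10x Matrix Market triplet directory (`matrix.mtx[.gz]`,
#' `features.tsv[.gz]`, `barcodes.tsv[.gz]`); when its feature-type column
#' declares both `"Gene Expression"` and `"Antibody Capture"` entries the
#' matrix is split into the two sources and `adtPath` may be omitted — and
#' (b) dense CSV with feature rows and cell columns (first column feature
#' ids, header cell ids), one file per source. Gzip is handled
#' transparently. Cells are intersected across sources and ordered as in
#' the RNA input; integer-ness of every entry is validated.
#'
#' @param rnaPath 10x directory or dense CSV with RNA counts.
#' @param adtPath dense CSV (or 10x directory) with ADT counts; optional
#'   when `rnaPath` is a 10x directory containing both feature types.
#' @return A [PairedCounts-class] object.
#' @export
readPairedCounts <- function(rnaPath, adtPath = NULL) {
  if (dir.exists(rnaPath)) {
    tenx <- .readTenx(rnaPath)
    isAdt <- tenx$type == "Antibody Capture"
    if (any(isAdt)) {
      rna <- tenx$counts[!isAdt, , drop = FALSE]
      adt <- tenx$counts[isAdt, , drop = FALSE]
      return(PairedCounts(rna, adt))
    }
    rna <- tenx$counts
  } else {
    rna <- .readDenseCsv(rnaPath)
  }
  if (is.null(adtPath))
    stop("adtPath is required unless the 10x input carries both ",
         "'Gene Expression' and 'Antibody Capture' features")
  adt <- if (dir.exists(adtPath)) .readTenx(adtPath)$counts
         else .readDenseCsv(adtPath)
  shared <- intersect(colnames(rna), colnames(adt))
  if (length(shared) == 0L)
    stop("RNA and ADT inputs share 0 cell barcodes (",
         ncol(rna), " vs ", ncol(adt), " cells)")
  if (length(shared) < ncol(rna) || length(shared) < ncol(adt))
    message("keeping ", length(shared), " cells present in both sources")
  PairedCounts(rna[, shared, drop = FALSE], adt[, shared, drop = FALSE])
}

#' Write paired counts to disk
#'
#' `format = "csv"` writes `rna.csv` and `adt.csv` (feature rows, cell
#' columns); `format = "10x"` writes one Matrix Market triplet directory
#' with both sources stacked and a feature-type column distinguishing
#' `"Gene Expression"` from `"Antibody Capture"`. Both round-trip through
#' [readPairedCounts()].
#'
#' @param x a [PairedCounts-class] object.
#' @param dir output directory (created if needed).
#' @param format `"csv"` or `"10x"`.
#' @return The output directory, invisibly.
#' @export
writePairedCounts <- function(x, dir, format = c("csv", "10x")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (format == "csv") {
    utils::write.csv(rnaCounts(x), file.path(dir, "rna.csv"))
    utils::write.csv(adtCounts(x), file.path(dir, "adt.csv"))
  } else {
    stacked <- rbind(rnaCounts(x), adtCounts(x))
    Matrix::writeMM(methods::as(Matrix::Matrix(stacked, sparse = TRUE),
                                "generalMatrix"),
                    file.path(dir, "matrix.mtx"))
    feats <- data.frame(
      id = rownames(stacked), name = rownames(stacked),
      type = c(rep("Gene Expression", nrow(rnaCounts(x))),
               rep("Antibody Capture", nrow(adtCounts(x)))))
    utils::write.table(feats, file.path(dir, "features.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    utils::write.table(colnames(rnaCounts(x)),
                       file.path(dir, "barcodes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

.hvgIndex <- function(X, nTop) {
  if (nTop > nrow(X)) stop("nTop exceeds the number of genes (", nrow(X), ")")
  v <- apply(.logNormalize(X), 1L, stats::var)
  order(-v, seq_len(nrow(X)))[seq_len(nTop)]
}

#' Keep the most variable genes
#'
#' Retains the `nTop` genes with the highest variance of log1p-normalized
#' expression, a simple variance-rank filter used to reduce dimension
#' before clustering. Ties are broken by gene index, so the result is
#' deterministic.
#'
#' @param x a counts matrix (features x cells) or a
#'   [PairedCounts-class] object (only the RNA part is filtered).
#' @param nTop number of genes to keep, at most the number of genes.
#' @return Object of the same class as `x`, reduced to `nTop` genes.
#' @export
setMethod("filterHVG", "matrix", function(x, nTop) {
  x[.hvgIndex(x, nTop), , drop = FALSE]
})

#' @rdname filterHVG
#' @export
setMethod("filterHVG", "PairedCounts", function(x, nTop) {
  x[.hvgIndex(rnaCounts(x), nTop), ]
})
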