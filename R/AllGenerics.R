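#' @rdname PairedCounts-accessors
#' @export
setGeneric("rnaCounts", function(x) standardGeneric("rnaCounts"))

#' @rdname PairedCounts-accessors
#' @export
setGeneric("adtCounts", function(x) standardGeneric("adtCounts"))

#' @rdname PairedCounts-accessors
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))

#' @rdname PairedCounts-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname PairedCounts-accessors
#' @export
setGeneric("markerIds", function(x) standardGeneric("markerIds"))

#' @rdname DMClusterResult-accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname DMClusterResult-accessors
#' @export
setGeneric("posteriorProbs", function(x) standardGeneric("posteriorProbs"))

#' @rdname filterHVG
#' @export
setGeneric("filterHVG", function(x, nTop) standardGeneric("filterHVG"))
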