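#' @include AllClasses.R
NULL

#' @rdname GenomeLayout-accessors
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' @rdname GenomeLayout-accessors
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @rdname GenomeLayout-accessors
#' @export
setGeneric("chromNames", function(x) standardGeneric("chromNames"))

#' @rdname GenomeLayout-accessors
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @rdname GenomeLayout-accessors
#' @export
setGeneric("genomeLayout", function(x) standardGeneric("genomeLayout"))

#' @rdname networkAccessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname networkAccessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname networkAccessors
#' @export
setGeneric("nodeOrigin", function(x) standardGeneric("nodeOrigin"))

#' @rdname networkAccessors
#' @export
setGeneric("datasetTag", function(x) standardGeneric("datasetTag"))

#' @rdname communityAccessors
#' @export
setGeneric("communityMembership", function(x) standardGeneric("communityMembership"))
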