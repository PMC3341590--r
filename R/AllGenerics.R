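#' @rdname exprValues
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname experimentOf
#' @export
setGeneric("experimentOf", function(x) standardGeneric("experimentOf"))

#' @rdname geneIds
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname conditionIds
#' @export
setGeneric("conditionIds", function(x) standardGeneric("conditionIds"))

#' @rdname nodeVectors
#' @export
setGeneric("nodeVectors", function(x) standardGeneric("nodeVectors"))

#' @rdname assignment
#' @export
setGeneric("assignment", function(x) standardGeneric("assignment"))

#' @rdname nodeSummary
#' @export
setGeneric("nodeSummary", function(x, ...) standardGeneric("nodeSummary"))
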