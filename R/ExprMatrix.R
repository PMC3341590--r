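#' Construct an ExprMatrix
#'
#' @param values Numeric matrix, genes in rows (unique rownames),
#'   conditions in columns (unique colnames). \code{NA} marks a missing
#'   measurement.
#' @param experiments Named character vector mapping every condition id
#'   to its experiment id, or a 2-column \code{data.frame}
#'   (condition, experiment).
#'
#' @return A validated \linkS4class{ExprMatrix}.
#' @examples
#' v <- matrix(c(11, 4, 6, 1, 2, 3), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("g1", "g2"), c("c1", "c2", "c3")))
#' em <- ExprMatrix(v, c(c1 = "expA", c2 = "expA", c3 = "expA"))
#' conditionIds(em)
#' @export
ExprMatrix <- function(values, experiments) {
    if (is.data.frame(experiments)) {
        if (ncol(experiments) < 2L)
            stop("experiments data.frame needs 2 columns (condition, experiment)")
        experiments <- stats::setNames(as.character(experiments[[2L]]),
                                       as.character(experiments[[1L]]))
    }
    if (is.null(colnames(values)))
        stop("values must have condition ids as colnames")
    missing_cond <- setdiff(colnames(values), names(experiments))
    if (length(missing_cond))
        stop("condition(s) without an experiment assignment: ",
             paste(missing_cond, collapse = ", "))
    cd <- S4Vectors::DataFrame(
        experiment = as.character(experiments[colnames(values)]),
        row.names = colnames(values))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = values), colData = cd)
    methods::new("ExprMatrix", se)
}

#' Expression values of an ExprMatrix
#'
#' @param x An \linkS4class{ExprMatrix}.
#' @return The gene x condition numeric matrix (\code{NA} = missing).
#' @rdname exprValues
#' @export
setMethod("exprValues", "ExprMatrix", function(x)
    SummarizedExperiment::assay(x, "exprs"))

#' Condition-to-experiment mapping
#'
#' @param x An \linkS4class{ExprMatrix}.
#' @return Named character vector: condition id -> experiment id.
#' @rdname experimentOf
#' @export
setMethod("experimentOf", "ExprMatrix", function(x)
    stats::setNames(as.character(SummarizedExperiment::colData(x)$experiment),
                    colnames(x)))

#' Gene identifiers
#'
#' @param x An \linkS4class{ExprMatrix} or \linkS4class{SOMMap}.
#' @rdname geneIds
#' @export
setMethod("geneIds", "ExprMatrix", function(x) rownames(x))

#' Condition identifiers
#'
#' @param x An \linkS4class{ExprMatrix} or \linkS4class{SOMMap}.
#' @rdname conditionIds
#' @export
setMethod("conditionIds", "ExprMatrix", function(x) colnames(x))

setMethod("show", "ExprMatrix", function(object) {
    v <- exprValues(object)
    ex <- experimentOf(object)
    cat("ExprMatrix:", nrow(v), "genes x", ncol(v), "conditions in",
        length(unique(ex)), "experiment(s)\n")
    cat(sprintf("  missing: %.1f%% of cells\n", 100 * mean(is.na(v))))
})
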