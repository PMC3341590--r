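## Expression matrix TSV: first row condition ids, first column gene ids.
## Missing values: empty cell or literal "NA" on read; written as "NA".

#' Read an expression matrix and its experiment grouping from TSV
#'
#' The matrix file is tab-separated with condition identifiers in the
#' first row and gene identifiers in the first column; empty cells and
#' the literal \code{NA} are read as missing. The experiments file is a
#' two-column TSV (condition id, experiment id) covering every
#' condition. Lines starting with \code{#} are ignored in both files.
#'
#' @param matrixPath Path to the expression matrix TSV.
#' @param experimentsPath Path to the condition-to-experiment TSV.
#' @return An \linkS4class{ExprMatrix}; row and column order follow the
#'   files.
#' @seealso [writeExprMatrix()]
#' @export
readExprMatrix <- function(matrixPath, experimentsPath) {
    for (p in c(matrixPath, experimentsPath))
        if (!file.exists(p)) stop("file not found: ", p)
    lines <- readLines(matrixPath)
    lines <- lines[!startsWith(lines, "#")]
    if (length(lines) < 2L)
        stop("format error in ", matrixPath,
             ": need a header row and at least one gene row")
    fields <- strsplit(lines, "\t", fixed = TRUE)
    conds <- fields[[1L]][-1L]
    if (length(conds) < 2L)
        stop("format error: at least two conditions are required")
    if (anyDuplicated(conds))
        stop("format error: duplicate condition id(s): ",
             paste(unique(conds[duplicated(conds)]), collapse = ", "))
    body <- fields[-1L]
    nf <- lengths(body)
    ## trailing empty cells are dropped by strsplit; pad them back
    if (any(nf > length(conds) + 1L))
        stop("format error: row with more cells than the header")
    genes <- vapply(body, `[`, character(1L), 1L)
    if (anyDuplicated(genes))
        stop("format error: duplicate gene id(s): ",
             paste(unique(genes[duplicated(genes)]), collapse = ", "))
    vals <- matrix(NA_real_, length(genes), length(conds),
                   dimnames = list(genes, conds))
    for (i in seq_along(body)) {
        cells <- body[[i]][-1L]
        length(cells) <- length(conds)
        miss <- is.na(cells) | cells == "" | cells == "NA"
        num <- suppressWarnings(as.numeric(cells))
        bad <- !miss & is.na(num)
        if (any(bad))
            stop("format error: non-numeric cell '", cells[which(bad)[1L]],
                 "' for gene ", genes[i])
        vals[i, ] <- ifelse(miss, NA_real_, num)
    }
    ed <- utils::read.table(experimentsPath, sep = "\t", header = FALSE,
                            colClasses = "character", comment.char = "#",
                            quote = "")
    if (ncol(ed) < 2L)
        stop("format error: experiments file needs 2 tab-separated columns")
    exps <- stats::setNames(ed[[2L]], ed[[1L]])
    uncovered <- setdiff(conds, names(exps))
    if (length(uncovered))
        stop("format error: condition(s) absent from experiments file: ",
             paste(uncovered, collapse = ", "))
    ExprMatrix(vals, exps)
}

#' Write an expression matrix (and optionally its grouping) to TSV
#'
#' Missing values are written as \code{NA}. The output is accepted by
#' [readExprMatrix()] (round-trip property).
#'
#' @param x An \linkS4class{ExprMatrix}.
#' @param matrixPath Output path for the matrix TSV.
#' @param experimentsPath Optional output path for the
#'   condition-to-experiment TSV.
#' @param header Optional character vector of comment lines (without the
#'   leading \code{#}) written before the data.
#' @return \code{matrixPath}, invisibly.
#' @export
writeExprMatrix <- function(x, matrixPath, experimentsPath = NULL,
                            header = NULL) {
    v <- exprValues(x)
    con <- file(matrixPath, "w")
    on.exit(close(con))
    if (!is.null(header))
        writeLines(paste0("# ", header), con)
    writeLines(paste(c("gene", colnames(v)), collapse = "\t"), con)
    body <- apply(v, 1L, function(row) {
        cells <- ifelse(is.na(row), "NA", sprintf("%.17g", row))
        paste(cells, collapse = "\t")
    })
    writeLines(paste(rownames(v), body, sep = "\t"), con)
    if (!is.null(experimentsPath)) {
        ex <- experimentOf(x)
        utils::write.table(data.frame(condition = names(ex),
                                      experiment = unname(ex)),
                           experimentsPath, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE)
    }
    invisible(matrixPath)
}
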