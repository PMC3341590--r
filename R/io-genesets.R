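#' Read gene sets from a plain list or a GMT file
#'
#' \code{"plain"}: one gene per line; the single set is named after the
#' file (basename without extension). \code{"gmt"}: standard GMT — each
#' tab-separated line holds set name, description, then members.
#' Members are de-duplicated; an empty set is a format error.
#'
#' @param path Input file path.
#' @param dialect \code{"plain"} or \code{"gmt"} (default guessed from
#'   the file extension).
#' @return A named list of \linkS4class{GeneSet} objects.
#' @export
readGeneSets <- function(path, dialect = NULL) {
    if (!file.exists(path)) stop("file not found: ", path)
    if (is.null(dialect))
        dialect <- if (grepl("\\.gmt$", path, ignore.case = TRUE))
            "gmt" else "plain"
    dialect <- match.arg(dialect, c("plain", "gmt"))
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (dialect == "plain") {
        members <- unique(trimws(lines))
        members <- members[nzchar(members)]
        if (!length(members))
            stop("format error: empty gene set in ", path)
        name <- sub("\\.[^.]*$", "", basename(path))
        sets <- list(methods::new("GeneSet", name = name, members = members))
    } else {
        if (!length(lines))
            stop("format error: empty GMT file ", path)
        fields <- strsplit(lines, "\t", fixed = TRUE)
        sets <- lapply(seq_along(fields), function(i) {
            f <- fields[[i]]
            if (length(f) < 3L)
                stop("format error at line ", i,
                     ": GMT needs name, description and >= 1 member")
            members <- unique(f[-(1:2)])
            members <- members[nzchar(members)]
            if (!length(members))
                stop("format error at line ", i, ": empty gene set '",
                     f[1L], "'")
            methods::new("GeneSet", name = f[1L], members = members)
        })
    }
    stats::setNames(sets, vapply(sets, function(s) s@name, character(1L)))
}
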