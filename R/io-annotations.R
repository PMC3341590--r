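#' Read gene-to-term annotations
#'
#' Two dialects are supported. \code{"two_column"}: a TSV with one
#' (gene id, term id) pair per line. \code{"gaf"}: GAF 2.x, using
#' column 2 (DB object id) and column 5 (term id), skipping
#' \code{!}-comment lines and rows whose qualifier (column 4) contains
#' \code{NOT}. Duplicate pairs are collapsed.
#'
#' @param path Input file path.
#' @param dialect \code{"two_column"} (default) or \code{"gaf"}.
#' @return An \linkS4class{AnnotationTable} with
#'   \code{propagated = FALSE}.
#' @seealso [propagateAnnotations()]
#' @export
readAnnotations <- function(path, dialect = c("two_column", "gaf")) {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path)
    if (dialect == "two_column") {
        keep <- nzchar(lines) & !startsWith(lines, "#")
        idx <- which(keep)
        fields <- strsplit(lines[keep], "\t", fixed = TRUE)
        bad <- lengths(fields) < 2L
        if (any(bad))
            stop("format error at line ", idx[which(bad)[1L]],
                 ": expected 2 tab-separated columns")
        genes <- vapply(fields, `[`, character(1L), 1L)
        terms <- vapply(fields, `[`, character(1L), 2L)
        if (any(!nzchar(genes)) || any(!nzchar(terms)))
            stop("format error: empty gene or term id at line ",
                 idx[which(!nzchar(genes) | !nzchar(terms))[1L]])
    } else {
        keep <- nzchar(lines) & !startsWith(lines, "!")
        idx <- which(keep)
        fields <- strsplit(lines[keep], "\t", fixed = TRUE)
        bad <- lengths(fields) < 5L
        if (any(bad))
            stop("format error at line ", idx[which(bad)[1L]],
                 ": GAF rows need >= 5 tab-separated columns")
        qual <- vapply(fields, `[`, character(1L), 4L)
        not <- vapply(strsplit(qual, "|", fixed = TRUE),
                      function(q) "NOT" %in% q, logical(1L))
        fields <- fields[!not]
        genes <- vapply(fields, `[`, character(1L), 2L)
        terms <- vapply(fields, `[`, character(1L), 5L)
    }
    if (!length(genes))
        stop("format error: no annotation rows in ", path)
    terms_by_gene <- lapply(split(terms, genes), function(t)
        sort(unique(t)))
    methods::new("AnnotationTable", terms = terms_by_gene,
                 termNames = character(), propagated = FALSE)
}

#' Parse a minimal OBO ontology
#'
#' Reads \code{[Term]} stanzas, keeping \code{id}, \code{is_a},
#' \code{relationship: part_of} (and any relation named in
#' \code{relations}), \code{name} and \code{is_obsolete}; obsolete terms
#' are dropped. This is sufficient for ancestor closure of annotations;
#' full OBO semantics are out of scope.
#'
#' @param path OBO 1.2 file path.
#' @param relations Relation names to traverse (default
#'   \code{c("is_a", "part_of")}).
#' @return A list with \code{parents} (named list term -> parent term
#'   ids) and \code{names} (named character term -> label).
#' @export
readOntology <- function(path, relations = c("is_a", "part_of")) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path)
    stanza_starts <- which(lines == "[Term]")
    if (!length(stanza_starts))
        stop("format error: no [Term] stanza in ", path)
    bounds <- c(stanza_starts, length(lines) + 1L)
    parents <- list()
    term_names <- character()
    for (s in seq_along(stanza_starts)) {
        chunk <- lines[(bounds[s] + 1L):(bounds[s + 1L] - 1L)]
        chunk <- chunk[!grepl("^\\[", chunk)]  # stop at next stanza header
        id <- sub("^id: *", "", grep("^id: ", chunk, value = TRUE))
        if (!length(id)) next
        id <- trimws(id[1L])
        if (any(grepl("^is_obsolete: *true", chunk))) next
        par <- character()
        if ("is_a" %in% relations) {
            isa <- sub("^is_a: *", "", grep("^is_a: ", chunk, value = TRUE))
            par <- c(par, sub(" *!.*$", "", isa))
        }
        rel_lines <- sub("^relationship: *", "",
                         grep("^relationship: ", chunk, value = TRUE))
        for (rl in rel_lines) {
            parts <- strsplit(trimws(sub(" *!.*$", "", rl)), " +")[[1L]]
            if (length(parts) >= 2L && parts[1L] %in% relations)
                par <- c(par, parts[2L])
        }
        parents[[id]] <- unique(trimws(par))
        nm <- sub("^name: *", "", grep("^name: ", chunk, value = TRUE))
        if (length(nm)) term_names[id] <- nm[1L]
    }
    list(parents = parents, names = term_names)
}

#' Propagate annotations to ancestor terms
#'
#' Closes each gene's term set under ancestor traversal along the chosen
#' ontology relations (transitive closure). Annotations are never
#' removed; the operation is idempotent. Terms absent from the ontology
#' are kept without ancestors, with a warning.
#'
#' @param annotations An \linkS4class{AnnotationTable}.
#' @param ontology Either an OBO file path or the list returned by
#'   [readOntology()].
#' @param relations Relations to traverse when \code{ontology} is a
#'   path.
#' @return A propagated \linkS4class{AnnotationTable}
#'   (\code{propagated = TRUE}).
#' @export
propagateAnnotations <- function(annotations, ontology,
                                 relations = c("is_a", "part_of")) {
    stopifnot(methods::is(annotations, "AnnotationTable"))
    if (is.character(ontology))
        ontology <- readOntology(ontology, relations)
    parents <- ontology$parents
    ## ancestors(): memoized transitive closure over the parent lists
    anc_cache <- new.env(parent = emptyenv())
    ancestors <- function(term) {
        if (!is.null(anc_cache[[term]])) return(anc_cache[[term]])
        out <- character()
        frontier <- parents[[term]]
        while (length(frontier)) {
            frontier <- setdiff(frontier, out)
            out <- c(out, frontier)
            frontier <- unique(unlist(parents[frontier], use.names = FALSE))
        }
        anc_cache[[term]] <- out
        out
    }
    all_terms <- unique(unlist(annotations@terms, use.names = FALSE))
    unknown <- setdiff(all_terms, names(parents))
    if (length(unknown))
        warning("term(s) absent from the ontology, kept without ancestors: ",
                paste(head(unknown, 5L), collapse = ", "),
                if (length(unknown) > 5L) " ...")
    closure <- lapply(stats::setNames(all_terms, all_terms), function(t)
        if (t %in% names(parents)) c(t, ancestors(t)) else t)
    new_terms <- lapply(annotations@terms, function(ts)
        sort(unique(unlist(closure[ts], use.names = FALSE))))
    nm <- annotations@termNames
    if (length(ontology$names))
        nm <- c(nm, ontology$names[setdiff(names(ontology$names), names(nm))])
    methods::new("AnnotationTable", terms = new_terms, termNames = nm,
                 propagated = TRUE)
}
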