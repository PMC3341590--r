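#' Filter terms by map-wide annotation frequency
#'
#' Terms annotating fewer than ten, or more than a quarter of, the genes
#' on the map are excluded as uninformative: a term is kept iff
#' \code{10 <= K <= floor(N / 4)}, where K is the number of mapped genes
#' carrying the term and N the number of mapped genes.
#'
#' @param annotations An \linkS4class{AnnotationTable}.
#' @param mappedGenes Character vector of genes on the map (the
#'   enrichment universe).
#' @return Character vector of retained term ids.
#' @export
filterTerms <- function(annotations, mappedGenes) {
    stopifnot(methods::is(annotations, "AnnotationTable"))
    terms <- annotations@terms[intersect(names(annotations@terms),
                                         mappedGenes)]
    if (!length(terms)) return(character())
    K <- table(unlist(terms, use.names = FALSE))
    N <- length(mappedGenes)
    names(K)[K >= 10 & K <= floor(N / 4)]
}

#' Upper-tail Fisher (hypergeometric) probability of over-representation
#'
#' Probability of observing \code{k} or more annotated genes in a
#' cluster of \code{n} genes when \code{K} of the \code{N} mapped genes
#' carry the term and genes are distributed at random between the
#' cluster and the rest of the map:
#' \code{p = sum_{i = k}^{min(n, K)} dhyper(i, K, N - K, n)}.
#'
#' @param k Annotated genes in the node.
#' @param K Annotated genes on the map.
#' @param n Genes in the node.
#' @param N Genes on the map.
#' @return One-sided p-value (vectorized over the arguments).
#' @export
fisherUpperTail <- function(k, K, n, N) {
    if (any(k < 0 | K < 0 | n < 0 | N < 0))
        stop("counts must be non-negative")
    if (any(K > N) || any(n > N))
        stop("K and n cannot exceed N")
    if (any(k > pmin(n, K)))
        stop("k cannot exceed min(n, K)")
    if (any(k < pmax(0, n + K - N)))
        stop("k below the minimum attainable overlap")
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' \code{q_(i) = min_{j >= i} (p_(j) * m / j)} clipped to 1, returned in
#' input order. \code{m} is the size of the test family and may exceed
#' \code{length(p)} when only a subset of the performed tests is being
#' adjusted.
#'
#' @param p Raw p-values in [0, 1].
#' @param m Family size (default \code{length(p)}).
#' @return Adjusted values in input order.
#' @export
bhFDR <- function(p, m = length(p)) {
    if (any(p < 0 | p > 1, na.rm = TRUE))
        stop("p-values must be in [0, 1]")
    if (m < length(p))
        stop("m must be at least length(p)")
    stats::p.adjust(p, method = "BH", n = m)
}

.termIncidence <- function(annotations, mappedGenes, termIds) {
    inc <- matrix(FALSE, length(mappedGenes), length(termIds),
                  dimnames = list(mappedGenes, termIds))
    terms <- annotations@terms[intersect(names(annotations@terms),
                                         mappedGenes)]
    for (g in names(terms)) {
        t <- intersect(terms[[g]], termIds)
        if (length(t)) inc[g, t] <- TRUE
    }
    inc
}

#' Per-node over-representation analysis
#'
#' For every occupied node and every term that passes [filterTerms()],
#' computes the hypergeometric contingency counts against the universe
#' of all mapped genes and the upper-tail Fisher probability, then
#' adjusts all performed tests jointly with the Benjamini-Hochberg
#' procedure. A (node, term) pair is \code{reported} iff its FDR is at
#' or below \code{fdrThreshold} AND at least four genes in the node
#' carry the term. Overlaps between parent and child terms are not
#' corrected for.
#'
#' @param map A trained \linkS4class{SOMMap}.
#' @param annotations An \linkS4class{AnnotationTable} (propagate first
#'   if ancestor-closed counting is wanted).
#' @param fdrThreshold Reporting threshold (default 0.05).
#' @return An \linkS4class{EnrichmentResults}.
#' @seealso [countEnrichedTerms()], [fisherUpperTail()], [bhFDR()]
#' @export
runEnrichment <- function(map, annotations, fdrThreshold = 0.05) {
    stopifnot(methods::is(map, "SOMMap"),
              methods::is(annotations, "AnnotationTable"))
    a <- map@assignment
    mapped <- a$gene
    N <- length(mapped)
    annotated <- intersect(names(annotations@terms), mapped)
    if (!length(annotated))
        stop("no annotated gene is on the map")
    termIds <- filterTerms(annotations, mapped)
    if (!length(termIds)) {
        return(methods::new("EnrichmentResults",
            table = data.frame(x = integer(), y = integer(),
                               term = character(), k = integer(),
                               K = integer(), n = integer(), N = integer(),
                               p_raw = numeric(), fdr = numeric(),
                               reported = logical()),
            nTests = 0L, fdrThreshold = fdrThreshold,
            termSignature = character()))
    }
    inc <- .termIncidence(annotations, mapped, termIds)
    node_idx <- a$y * map@config@width + a$x
    occupied <- sort(unique(node_idx))
    node_fac <- factor(node_idx, levels = occupied)
    ## k: occupied-node x term matrix of annotated-in-node counts
    kmat <- rowsum(inc + 0L, node_fac)
    nvec <- as.integer(table(node_fac))
    Kvec <- colSums(inc)
    tab <- data.frame(
        x = rep(occupied %% map@config@width, times = length(termIds)),
        y = rep(occupied %/% map@config@width, times = length(termIds)),
        term = rep(termIds, each = length(occupied)),
        k = as.integer(kmat),
        K = rep(as.integer(Kvec), each = length(occupied)),
        n = rep(nvec, times = length(termIds)),
        N = N, stringsAsFactors = FALSE)
    tab$p_raw <- fisherUpperTail(tab$k, tab$K, tab$n, tab$N)
    tab$fdr <- bhFDR(tab$p_raw)
    tab$reported <- tab$fdr <= fdrThreshold & tab$k >= 4L
    tab <- tab[order(tab$fdr, tab$p_raw), ]
    rownames(tab) <- NULL
    sig <- vapply(termIds, function(t)
        paste(sort(rownames(inc)[inc[, t]]), collapse = "\r"),
        character(1L))
    methods::new("EnrichmentResults", table = tab, nTests = nrow(tab),
                 fdrThreshold = fdrThreshold, termSignature = sig)
}

#' Count distinct enriched terms at one or more thresholds
#'
#' For each threshold, counts the DISTINCT terms enriched anywhere on
#' the map at \code{fdr <= threshold} (with the >= 4 genes-in-node
#' filter), after redundancy collapse: terms annotating exactly the same
#' set of mapped genes count once.
#'
#' @param results An \linkS4class{EnrichmentResults}.
#' @param thresholds Numeric vector of FDR thresholds.
#' @return Named integer vector of counts, one per threshold.
#' @export
countEnrichedTerms <- function(results, thresholds) {
    stopifnot(methods::is(results, "EnrichmentResults"))
    tab <- results@table
    vapply(stats::setNames(thresholds, format(thresholds)),
           function(th) {
               hit <- tab$fdr <= th & tab$k >= 4L
               length(unique(results@termSignature[unique(tab$term[hit])]))
           }, integer(1L))
}

#' Write enrichment results as TSV
#'
#' @param results An \linkS4class{EnrichmentResults}.
#' @param path Output path; columns x, y, term, k, K, n, N, p_raw, fdr,
#'   reported.
#' @param header Optional comment lines (leading \code{#}).
#' @return \code{path}, invisibly.
#' @export
writeEnrichment <- function(results, path, header = NULL) {
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(header)) writeLines(paste0("# ", header), con)
    utils::write.table(results@table, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

setMethod("show", "EnrichmentResults", function(object) {
    cat("EnrichmentResults:", object@nTests, "(node, term) tests,",
        sum(object@table$reported), "reported at FDR <=",
        object@fdrThreshold, "\n")
})
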