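#' Select map nodes by a node-vector component inequality
#'
#' Returns the set of nodes whose node-vector component for one
#' condition passes a simple arithmetic threshold — the mechanism behind
#' map region outlines such as "embryo expression greater than 0.25".
#' Compound regions are set algebra on the returned node sets
#' ([unionRegions()], [intersectRegions()]).
#'
#' @param map A \linkS4class{SOMMap}.
#' @param condition Condition id (a component of the node vectors).
#' @param comparator \code{"greater_than"} or \code{"less_than"}
#'   (aliases \code{">"}, \code{"<"}).
#' @param threshold Numeric threshold.
#' @return \code{data.frame} of node coordinates (\code{x}, \code{y});
#'   possibly empty.
#' @export
selectNodes <- function(map, condition, comparator = "greater_than",
                        threshold = 0) {
    stopifnot(methods::is(map, "SOMMap"))
    comparator <- match.arg(comparator,
                            c("greater_than", "less_than", ">", "<"))
    j <- match(condition, map@conditionIds)
    if (is.na(j))
        stop("unknown condition: ", condition)
    comp <- map@codebook[, j]
    keep <- if (comparator %in% c("greater_than", ">"))
        comp > threshold else comp < threshold
    coords <- .gridCoords(map@config)
    out <- as.data.frame(coords[keep, , drop = FALSE])
    rownames(out) <- NULL
    out
}

#' @rdname unionRegions
#' @export
unionRegions <- function(a, b) {
    out <- unique(rbind(a[, c("x", "y")], b[, c("x", "y")]))
    out <- out[order(out$y, out$x), ]
    rownames(out) <- NULL
    out
}

#' Set algebra on node regions
#'
#' Regions are plain node sets (\code{data.frame}s of \code{x},
#' \code{y}); compound multi-condition regions combine them with union
#' and intersection.
#'
#' @param a,b Regions as returned by [selectNodes()].
#' @return The combined region, ordered by (y, x).
#' @rdname unionRegions
#' @export
intersectRegions <- function(a, b) {
    key <- function(r) paste(r$x, r$y)
    out <- a[key(a) %in% key(b), c("x", "y")]
    out <- out[order(out$y, out$x), ]
    rownames(out) <- NULL
    out
}

#' Group a region into 4-connected components
#'
#' Splits a node set into its connected components under 4-connectivity
#' (nodes touching horizontally or vertically). Drawing contiguous
#' outlines around components is presentation; the components themselves
#' are the exportable structure.
#'
#' @param region \code{data.frame} of node coordinates (\code{x},
#'   \code{y}).
#' @return The region with an added integer \code{component} column
#'   (1-based, ordered by first member in (y, x) order).
#' @export
regionComponents <- function(region) {
    n <- nrow(region)
    comp <- integer(n)
    if (!n) return(cbind(region, component = integer()))
    key <- paste(region$x, region$y)
    next_comp <- 0L
    for (i in order(region$y, region$x)) {
        if (comp[i]) next
        next_comp <- next_comp + 1L
        frontier <- i
        comp[i] <- next_comp
        while (length(frontier)) {
            cur <- frontier[1L]
            frontier <- frontier[-1L]
            nb_keys <- paste(region$x[cur] + c(1L, -1L, 0L, 0L),
                             region$y[cur] + c(0L, 0L, 1L, -1L))
            hits <- which(key %in% nb_keys & comp == 0L)
            comp[hits] <- next_comp
            frontier <- c(frontier, hits)
        }
    }
    cbind(region, component = comp)
}

#' Per-node gene-category overlay counts
#'
#' Counts, for every node, the total assigned genes and the members of
#' each gene category mapping there — the numbers behind per-node pie
#' overlays. A gene belonging to several categories contributes once to
#' each; per category, counts over nodes sum to the size of the
#' category's intersection with the mapped genes.
#'
#' @param map A trained \linkS4class{SOMMap}.
#' @param categories A list of \linkS4class{GeneSet}s (or one
#'   \linkS4class{GeneSet}).
#' @return \code{data.frame} with one row per node: \code{x}, \code{y},
#'   \code{total}, then one count column per category.
#' @export
overlayCounts <- function(map, categories) {
    stopifnot(methods::is(map, "SOMMap"))
    if (methods::is(categories, "GeneSet")) categories <- list(categories)
    summ <- nodeSummary(map)
    out <- data.frame(x = summ$x, y = summ$y, total = summ$count)
    a <- map@assignment
    idx <- a$y * map@config@width + a$x + 1L
    for (cat in categories) {
        stopifnot(methods::is(cat, "GeneSet"))
        inset <- a$gene %in% cat@members
        if (!any(inset))
            warning("category '", cat@name,
                    "' has no member on the map")
        out[[cat@name]] <- as.integer(
            tabulate(idx[inset], nbins = nrow(summ)))
    }
    out
}
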