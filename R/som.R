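#' Construct a SOM training configuration
#'
#' Defaults are the published genome-scale settings: 25 x 20 grid,
#' starting learning rate 0.1, starting neighbourhood radius 10, on
#' average 20 presentations per gene, Pearson similarity with missing
#' values excluded pairwise, and a flat ("bubble") neighbourhood on
#' city-block grid distance.
#'
#' @param width,height Grid dimensions.
#' @param lr0 Starting learning rate, in (0, 1].
#' @param radius0 Starting neighbourhood radius (grid units).
#' @param presentationsPerGene Average presentations of each gene.
#' @param metric \code{"pearson"} or \code{"euclidean"}.
#' @param seed Integer RNG seed.
#' @param minOverlap Minimum jointly observed components for a defined
#'   similarity.
#' @param gridMetric \code{"cityblock"} or \code{"chebyshev"}.
#' @param kernel \code{"bubble"} or \code{"gaussian"}.
#' @return A validated \linkS4class{SOMConfig}.
#' @export
SOMConfig <- function(width = 25L, height = 20L, lr0 = 0.1, radius0 = 10,
                      presentationsPerGene = 20, metric = "pearson",
                      seed = 1L, minOverlap = 3L,
                      gridMetric = "cityblock", kernel = "bubble") {
    methods::new("SOMConfig", width = as.integer(width),
                 height = as.integer(height), lr0 = lr0, radius0 = radius0,
                 presentationsPerGene = presentationsPerGene,
                 metric = metric, seed = as.integer(seed),
                 minOverlap = as.integer(minOverlap),
                 gridMetric = gridMetric, kernel = kernel)
}

## 0-based node coordinates in row-major order: node i (1-based R index)
## sits at x = (i-1) %% width, y = (i-1) %/% width. which.max() over this
## order implements the (y, x)-lexicographic BMU tie-break.
.gridCoords <- function(config) {
    i <- seq_len(config@width * config@height) - 1L
    cbind(x = i %% config@width, y = i %/% config@width)
}

.gridDist <- function(coords, at, gridMetric) {
    dx <- abs(coords[, 1L] - at[1L])
    dy <- abs(coords[, 2L] - at[2L])
    if (gridMetric == "cityblock") dx + dy else pmax(dx, dy)
}

## Linear decay schedule: alpha(t) = lr0 * (1 - t/T), r(t) = radius0 *
## (1 - t/T) for presentation index t in 0..T-1; both reach 0 at t = T.
.schedule <- function(t, total, lr0, radius0) {
    frac <- 1 - t / total
    c(alpha = lr0 * frac, radius = radius0 * frac)
}

## Similarity of one (possibly incomplete) profile against every node
## vector. Returns -Inf for "incomparable" (overlap below minOverlap, or
## zero variance over the overlap under the Pearson metric), which can
## never win a BMU search.
.simToNodes <- function(x, codebook, metric, minOverlap) {
    obs <- which(!is.na(x))
    n <- length(obs)
    none <- rep(-Inf, nrow(codebook))
    if (n < minOverlap) return(none)
    xo <- x[obs]
    M <- codebook[, obs, drop = FALSE]
    if (metric == "pearson") {
        xc <- xo - mean(xo)
        sx2 <- sum(xc^2)
        if (sx2 <= 1e-12) return(none)
        num <- drop(M %*% xc)
        den <- rowSums(M^2) - n * rowMeans(M)^2
        bad <- den <= 1e-12
        r <- num / sqrt(pmax(den, 1e-300) * sx2)
        r <- pmin(pmax(r, -1), 1)
        r[bad] <- -Inf
        r
    } else {
        d2 <- rowSums(M^2) - 2 * drop(M %*% xo) + sum(xo^2)
        -sqrt(pmax(d2, 0) / n)
    }
}

#' Similarity between two profiles with missing values
#'
#' Computes the similarity used for best-matching-unit search over the
#' components observed in both vectors. \code{"pearson"}: the Pearson
#' correlation over the joint overlap, in [-1, 1] (missing values are
#' simply excluded from the calculation). \code{"euclidean"}: the
#' negated Euclidean distance over the overlap, normalized by the square
#' root of the overlap size so profiles with different missingness are
#' comparable. Higher is more similar under both metrics.
#'
#' If the overlap has fewer than \code{minOverlap} components, or either
#' vector has zero variance over the overlap under the Pearson metric,
#' the pair is incomparable and \code{-Inf} is returned: such a score
#' can never win a BMU contest.
#'
#' @param u,v Numeric vectors of equal length; \code{NA} = missing.
#' @param metric \code{"pearson"} (default) or \code{"euclidean"}.
#' @param minOverlap Minimum jointly observed components (default 3).
#' @return A single similarity score, or \code{-Inf} if incomparable.
#' @examples
#' similarity(c(1, 2, 3), c(1, 2, 4))          # 9/sqrt(84)
#' similarity(c(1, NA, 3, 4), c(0, 7, 2, 3))   # overlap (1,3,4) vs (0,2,3)
#' @export
similarity <- function(u, v, metric = c("pearson", "euclidean"),
                       minOverlap = 3L) {
    metric <- match.arg(metric)
    if (length(u) != length(v)) stop("u and v must have the same length")
    obs <- which(!is.na(u) & !is.na(v))
    if (length(obs) < minOverlap) return(-Inf)
    uo <- u[obs]; vo <- v[obs]
    if (metric == "pearson") {
        if (stats::sd(uo) == 0 || stats::sd(vo) == 0) return(-Inf)
        stats::cor(uo, vo)
    } else {
        -sqrt(sum((uo - vo)^2) / length(obs))
    }
}

## One training presentation: update the BMU's neighbourhood towards the
## input. Components missing in the input never change node components.
.somUpdate <- function(codebook, coords, bmu, xg, alpha, radius,
                       gridMetric, kernel) {
    d <- .gridDist(coords, coords[bmu, ], gridMetric)
    nb <- which(d <= radius)
    h <- if (kernel == "bubble")
        rep(alpha, length(nb))
    else
        alpha * exp(-d[nb]^2 / (2 * max(radius / 2, 0.5)^2))
    obs <- which(!is.na(xg))
    W <- codebook[nb, obs, drop = FALSE]
    target <- matrix(xg[obs], length(nb), length(obs), byrow = TRUE)
    codebook[nb, obs] <- W + h * (target - W)
    codebook
}

.initCodebook <- function(config, values) {
    n_nodes <- config@width * config@height
    codebook <- matrix(0, n_nodes, ncol(values),
                       dimnames = list(NULL, colnames(values)))
    for (j in seq_len(ncol(values))) {
        col <- values[, j]
        col <- col[!is.na(col)]
        if (!length(col))
            stop("condition '", colnames(values)[j],
                 "' has no observed values")
        codebook[, j] <- stats::runif(n_nodes, min(col), max(col))
    }
    codebook
}

#' Randomly initialize a map within the range of the data
#'
#' Each node-vector component for condition c is drawn uniformly from
#' the [min, max] of the observed values of c across all genes.
#' Deterministic given \code{config@seed}.
#'
#' @param config A \linkS4class{SOMConfig}.
#' @param x An \linkS4class{ExprMatrix}.
#' @return An untrained \linkS4class{SOMMap} with an empty assignment.
#' @export
initMap <- function(config, x) {
    stopifnot(methods::is(x, "ExprMatrix"))
    set.seed(config@seed)
    codebook <- .initCodebook(config, exprValues(x))
    methods::new("SOMMap", config = config, codebook = codebook,
                 conditionIds = colnames(x),
                 assignment = data.frame(gene = character(),
                                         x = integer(), y = integer()))
}

#' Train a self-organizing map on expression profiles
#'
#' Implements competitive learning: the map is randomly initialized
#' within the range of the data, then gene profiles are presented at
#' random (with replacement), on average
#' \code{presentationsPerGene} times each. At each presentation the
#' best-matching unit (highest similarity; ties broken towards the
#' smallest (y, x)) and its neighbours within the current radius are
#' updated towards the input by the current learning rate; both decay
#' linearly to zero over training. Components missing in the input leave
#' the corresponding node components unchanged. After training, every
#' gene is assigned to its closest node under the final node vectors.
#'
#' The whole procedure is deterministic given \code{config@seed}.
#'
#' @param x An \linkS4class{ExprMatrix} (typically median-shift
#'   normalized).
#' @param config A \linkS4class{SOMConfig}.
#' @return A trained \linkS4class{SOMMap}.
#' @seealso [assignGenes()], [nodeSummary()], [medianShift()]
#' @export
trainSOM <- function(x, config = SOMConfig()) {
    stopifnot(methods::is(x, "ExprMatrix"))
    v <- exprValues(x)
    set.seed(config@seed)
    codebook <- .initCodebook(config, v)
    coords <- .gridCoords(config)
    n_genes <- nrow(v)
    total <- as.integer(round(config@presentationsPerGene * n_genes))
    presented <- sample.int(n_genes, total, replace = TRUE)
    for (t in seq_len(total)) {
        sched <- .schedule(t - 1L, total, config@lr0, config@radius0)
        g <- presented[t]
        xg <- v[g, ]
        sims <- .simToNodes(xg, codebook, config@metric, config@minOverlap)
        if (!any(is.finite(sims)))
            stop("gene '", rownames(v)[g],
                 "' is incomparable to every node")
        bmu <- which.max(sims)
        codebook <- .somUpdate(codebook, coords, bmu, xg,
                               sched[["alpha"]], sched[["radius"]],
                               config@gridMetric, config@kernel)
    }
    map <- methods::new("SOMMap", config = config, codebook = codebook,
                        conditionIds = colnames(v),
                        assignment = data.frame(gene = character(),
                                                x = integer(),
                                                y = integer()))
    assignGenes(x, map)
}

#' Assign genes to their closest map node
#'
#' Finds, for every gene, the node with maximal similarity under the
#' map's metric (ties broken towards the smallest (y, x) coordinate);
#' identical profiles receive identical nodes.
#'
#' @param x An \linkS4class{ExprMatrix} sharing the map's condition ids.
#' @param map A \linkS4class{SOMMap}.
#' @return A \linkS4class{SOMMap} with the assignment replaced.
#' @export
assignGenes <- function(x, map) {
    stopifnot(methods::is(x, "ExprMatrix"), methods::is(map, "SOMMap"))
    if (!identical(colnames(x), map@conditionIds))
        stop("matrix and map condition ids differ")
    v <- exprValues(x)
    cfg <- map@config
    coords <- .gridCoords(cfg)
    bmu <- integer(nrow(v))
    for (g in seq_len(nrow(v))) {
        sims <- .simToNodes(v[g, ], map@codebook, cfg@metric,
                            cfg@minOverlap)
        if (!any(is.finite(sims)))
            stop("gene '", rownames(v)[g],
                 "' is incomparable to every node")
        bmu[g] <- which.max(sims)
    }
    methods::new("SOMMap", config = cfg, codebook = map@codebook,
                 conditionIds = map@conditionIds,
                 assignment = data.frame(gene = rownames(v),
                                         x = coords[bmu, 1L],
                                         y = coords[bmu, 2L],
                                         stringsAsFactors = FALSE))
}

#' Per-node occupancy summary
#'
#' @param x A trained \linkS4class{SOMMap}.
#' @param ... Ignored.
#' @return \code{data.frame} with one row per node (empty nodes
#'   included, count 0): \code{x}, \code{y}, \code{count} and a
#'   list-column \code{genes}. Counts sum to the number of assigned
#'   genes.
#' @rdname nodeSummary
#' @export
setMethod("nodeSummary", "SOMMap", function(x, ...) {
    cfg <- x@config
    coords <- .gridCoords(cfg)
    a <- x@assignment
    idx <- a$y * cfg@width + a$x + 1L
    members <- split(a$gene, factor(idx, levels = seq_len(nrow(coords))))
    data.frame(x = coords[, 1L], y = coords[, 2L],
               count = lengths(members),
               genes = I(unname(members)), row.names = NULL)
})

#' @rdname nodeVectors
#' @param x A \linkS4class{SOMMap}.
#' @return \code{nodeVectors()}: the codebook matrix (nodes x
#'   conditions, row-major node order).
#' @export
setMethod("nodeVectors", "SOMMap", function(x) x@codebook)

#' @rdname assignment
#' @param x A \linkS4class{SOMMap}.
#' @return \code{assignment()}: \code{data.frame} with columns
#'   \code{gene}, \code{x}, \code{y}.
#' @export
setMethod("assignment", "SOMMap", function(x) x@assignment)

#' @rdname geneIds
#' @export
setMethod("geneIds", "SOMMap", function(x) x@assignment$gene)

#' @rdname conditionIds
#' @export
setMethod("conditionIds", "SOMMap", function(x) x@conditionIds)

setMethod("show", "SOMMap", function(object) {
    cfg <- object@config
    cat("SOMMap:", cfg@width, "x", cfg@height, "grid (",
        cfg@width * cfg@height, "nodes ),", nrow(object@assignment),
        "genes assigned,", length(object@conditionIds), "conditions\n")
    cat("  metric:", cfg@metric, " seed:", cfg@seed, "\n")
})
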