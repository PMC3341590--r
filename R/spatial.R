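#' Mean city-block distance to the closest within-set neighbour
#'
#' For each member position, the city-block distance |dx| + |dy| to the
#' nearest OTHER member is found (co-located members give 0); the mean
#' over members is returned. Used as the observed statistic of the
#' spatial non-randomness test.
#'
#' @param positions Two-column matrix or data.frame of (x, y) node
#'   coordinates, one row per gene (at least 2 rows).
#' @return The mean nearest-neighbour distance.
#' @examples
#' meanNNDistance(rbind(c(0, 0), c(1, 2), c(5, 5)))  # 13/3
#' @export
meanNNDistance <- function(positions) {
    positions <- as.matrix(positions)
    n <- nrow(positions)
    if (n < 2L) stop("at least 2 positions are required")
    dx <- abs(outer(positions[, 1L], positions[, 1L], "-"))
    dy <- abs(outer(positions[, 2L], positions[, 2L], "-"))
    d <- dx + dy
    diag(d) <- Inf
    mean(apply(d, 1L, min))
}

#' Empirical non-randomness test for a gene set on the map
#'
#' Tests whether a gene set is spatially clustered on the map even when
#' it is not confined to a single node. The observed statistic d is the
#' mean city-block distance of each member to its closest within-set
#' neighbour; sets of the same size are then sampled from the mapped
#' genes (uniformly, without replacement) \code{nSamples} times and the
#' same statistic d' computed. The estimated p-value is the fraction of
#' samples with d' strictly below d; ties count as "not smaller", so a
#' p of exactly 0 is reportable (the add-one estimate
#' \code{(count + 1) / (nSamples + 1)} is also returned). Where several
#' sets are tested, a Bonferroni correction multiplies p by
#' \code{nTests}.
#'
#' @param map A trained \linkS4class{SOMMap}.
#' @param geneSet A \linkS4class{GeneSet} or character vector of gene
#'   ids. Members absent from the map are dropped with a warning; at
#'   least 2 mapped members are required.
#' @param nSamples Null samples to draw (default 100).
#' @param nTests Bonferroni factor (default 1).
#' @param seed Integer seed; fixes the null samples.
#' @param scaleSamplesByTests If \code{TRUE}, draw
#'   \code{nSamples * nTests} samples instead, so the attainable p
#'   resolution matches the corrected scale.
#' @return A \linkS4class{SpatialTestResult}.
#' @export
nonrandomTest <- function(map, geneSet, nSamples = 100L, nTests = 1L,
                          seed = 1L, scaleSamplesByTests = FALSE) {
    stopifnot(methods::is(map, "SOMMap"))
    if (methods::is(geneSet, "GeneSet")) {
        name <- geneSet@name
        members <- geneSet@members
    } else {
        name <- "gene_set"
        members <- unique(as.character(geneSet))
    }
    a <- map@assignment
    hit <- members %in% a$gene
    if (any(!hit))
        warning(sum(!hit), " member(s) of '", name,
                "' absent from the map were dropped")
    members <- members[hit]
    n <- length(members)
    if (n < 2L)
        stop("gene set '", name, "' has fewer than 2 mapped members")
    pos <- as.matrix(a[match(members, a$gene), c("x", "y")])
    d_obs <- meanNNDistance(pos)
    if (scaleSamplesByTests) nSamples <- nSamples * nTests
    all_pos <- as.matrix(a[, c("x", "y")])
    set.seed(seed)
    count_lower <- 0L
    for (s in seq_len(nSamples)) {
        idx <- sample.int(nrow(all_pos), n)
        if (meanNNDistance(all_pos[idx, , drop = FALSE]) < d_obs)
            count_lower <- count_lower + 1L
    }
    p_raw <- count_lower / nSamples
    methods::new("SpatialTestResult", setName = name, n = n,
                 dObserved = d_obs, nSamples = as.integer(nSamples),
                 countLower = count_lower, pRaw = p_raw,
                 pCorrected = min(1, p_raw * nTests),
                 pConservative = (count_lower + 1) / (nSamples + 1),
                 nTests = as.integer(nTests))
}

setMethod("show", "SpatialTestResult", function(object) {
    cat("SpatialTestResult '", object@setName, "': n = ", object@n,
        ", d = ", format(object@dObserved, digits = 4L),
        ", p_raw = ", object@pRaw, " (", object@countLower, "/",
        object@nSamples, "), p_corrected = ", object@pCorrected, "\n",
        sep = "")
})

## Within-node pair bookkeeping for reproducibility sampling: nodes are
## weighted by their pair count choose(c, 2).
.withinNodePairs <- function(map) {
    a <- map@assignment
    idx <- a$y * map@config@width + a$x
    members <- split(a$gene, idx)
    members <- members[lengths(members) >= 2L]
    if (!length(members)) stop("no node of the map holds >= 2 genes")
    list(members = members,
         weights = vapply(members, function(g) choose(length(g), 2),
                          numeric(1L)))
}

#' Co-clustering reproducibility across independently seeded maps
#'
#' Samples co-clustered gene pairs from the main map (uniformly over the
#' multiset of all within-node pairs, i.e. nodes weighted by their pair
#' count) and looks the pair up on a randomly chosen alternate map. A
#' pair counts as "same" when assigned identical nodes there and "near"
#' when the two assignments lie within \code{nearRadius} grid units
#' (city-block).
#'
#' @param main The reference \linkS4class{SOMMap}.
#' @param alternates A list of \linkS4class{SOMMap}s over the same gene
#'   universe (typically re-trainings with different seeds).
#' @param nPairs Pairs to sample (default 50000).
#' @param nearRadius "Nearby" grid distance (default 5).
#' @param seed Integer seed.
#' @return A \linkS4class{ReproducibilityResult}.
#' @export
coclusterReproducibility <- function(main, alternates, nPairs = 50000L,
                                     nearRadius = 5L, seed = 1L) {
    stopifnot(methods::is(main, "SOMMap"), length(alternates) >= 1L)
    if (methods::is(alternates, "SOMMap")) alternates <- list(alternates)
    main_genes <- sort(main@assignment$gene)
    for (alt in alternates) {
        stopifnot(methods::is(alt, "SOMMap"))
        if (!identical(sort(alt@assignment$gene), main_genes))
            stop("all maps must share the same gene universe")
    }
    wp <- .withinNodePairs(main)
    lookup <- lapply(alternates, function(alt) {
        a <- alt@assignment
        m <- as.matrix(a[, c("x", "y")])
        rownames(m) <- a$gene
        m
    })
    set.seed(seed)
    node_draw <- sample.int(length(wp$members), nPairs, replace = TRUE,
                            prob = wp$weights)
    alt_draw <- sample.int(length(alternates), nPairs, replace = TRUE)
    n_same <- 0L
    n_near <- 0L
    for (i in seq_len(nPairs)) {
        g <- wp$members[[node_draw[i]]]
        pair <- g[sample.int(length(g), 2L)]
        pos <- lookup[[alt_draw[i]]][pair, , drop = FALSE]
        d <- abs(pos[1L, 1L] - pos[2L, 1L]) + abs(pos[1L, 2L] - pos[2L, 2L])
        if (d == 0L) n_same <- n_same + 1L
        if (d <= nearRadius) n_near <- n_near + 1L
    }
    methods::new("ReproducibilityResult", nPairs = as.integer(nPairs),
                 nSame = n_same, nNear = n_near,
                 fracSame = n_same / nPairs, fracNear = n_near / nPairs,
                 nearRadius = as.integer(nearRadius))
}

setMethod("show", "ReproducibilityResult", function(object) {
    cat(sprintf(paste0("ReproducibilityResult: %d pairs, %.1f%% same",
                       " node, %.1f%% within %d grid units\n"),
                object@nPairs, 100 * object@fracSame,
                100 * object@fracNear, object@nearRadius))
})
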