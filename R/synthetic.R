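## All randomness in the generators flows from one user seed via
## substream seeds, so adding draws to one stage cannot silently shift
## another stage's stream.
.splitSeed <- function(seed, k) {
    (as.numeric(seed) * 48271 + k) %% (2^31 - 1)
}

#' Simulate a multi-experiment expression matrix with planted clusters
#'
#' Emulates the structure of a curated multi-publication expression
#' compendium: several experiment blocks of a few conditions each,
#' planted co-expression clusters, per-cell missing values, and
#' heterogeneous dynamic range across experiments (some experiments span
#' a wide range of values, others a narrow one). Each cluster has an
#' archetype profile (independent normal draws with sd
#' \code{clusterSd}, scaled per experiment by its range multiplier);
#' each gene is its cluster's archetype plus independent observation
#' noise (sd \code{noiseSd}); cells are masked missing independently at
#' \code{missingRate}, re-drawing a gene's mask if fewer than 3 of its
#' values would remain observed. No attempt is made to reproduce real
#' measured values.
#'
#' The defaults describe the validation conditions used throughout the
#' package's tests: 2000 genes, 4 experiment blocks totalling 20
#' conditions, 10 clusters, noise sd at 0.3 of the cluster sd, 5%
#' missing cells.
#'
#' @param nGenes Number of genes.
#' @param experimentBlocks Named integer vector: conditions per
#'   experiment.
#' @param nClusters Planted co-expression clusters
#'   (\code{<= nGenes}).
#' @param clusterSd Spread of archetype values.
#' @param noiseSd Per-gene observation noise sd.
#' @param missingRate Independent missingness probability, in [0, 1).
#' @param rangeMultipliers Per-experiment scale factors (named like
#'   \code{experimentBlocks}); defaults emulate mixed wide/narrow
#'   dynamic ranges.
#' @param seed Integer seed; the generator is fully deterministic given
#'   it.
#' @return A list: \code{matrix} (an \linkS4class{ExprMatrix}) and
#'   \code{truth} (list with \code{clusterOf}, a named integer vector,
#'   and \code{archetypes}, a cluster x condition matrix).
#' @seealso [simulateAnnotations()]
#' @export
simulateExpression <- function(nGenes = 2000L,
                               experimentBlocks = c(expA = 6L, expB = 6L,
                                                    expC = 5L, expD = 3L),
                               nClusters = 10L, clusterSd = 1,
                               noiseSd = 0.3, missingRate = 0.05,
                               rangeMultipliers = NULL, seed = 1L) {
    if (nClusters > nGenes) stop("nClusters must be <= nGenes")
    if (missingRate < 0 || missingRate >= 1)
        stop("missingRate must be in [0, 1)")
    if (clusterSd < 0 || noiseSd < 0)
        stop("clusterSd and noiseSd must be non-negative")
    if (is.null(names(experimentBlocks)))
        names(experimentBlocks) <- paste0("exp", seq_along(experimentBlocks))
    if (is.null(rangeMultipliers))
        rangeMultipliers <- stats::setNames(
            rep_len(c(2, 1, 0.5, 1.5), length(experimentBlocks)),
            names(experimentBlocks))
    conds <- unlist(lapply(names(experimentBlocks), function(e)
        paste0(e, "_c", seq_len(experimentBlocks[[e]]))))
    exp_of <- stats::setNames(
        rep(names(experimentBlocks), times = experimentBlocks), conds)
    n_cond <- length(conds)
    genes <- sprintf("gene%04d", seq_len(nGenes))

    set.seed(.splitSeed(seed, 1))
    cluster_of <- stats::setNames(sample(rep_len(seq_len(nClusters),
                                                 nGenes)), genes)
    set.seed(.splitSeed(seed, 2))
    mult <- rep(rangeMultipliers[exp_of], each = 1L)
    archetypes <- matrix(stats::rnorm(nClusters * n_cond, 0, clusterSd),
                         nClusters, n_cond,
                         dimnames = list(NULL, conds))
    archetypes <- sweep(archetypes, 2L, unname(mult), `*`)
    set.seed(.splitSeed(seed, 3))
    values <- archetypes[cluster_of, , drop = FALSE] +
        matrix(stats::rnorm(nGenes * n_cond, 0, noiseSd), nGenes, n_cond)
    dimnames(values) <- list(genes, conds)
    if (missingRate > 0) {
        set.seed(.splitSeed(seed, 4))
        mask <- matrix(stats::runif(nGenes * n_cond) < missingRate,
                       nGenes, n_cond)
        ## keep >= 3 observed values per gene so every gene stays
        ## comparable under the default minOverlap
        for (i in seq_len(nGenes)) {
            while (sum(!mask[i, ]) < 3L)
                mask[i, ] <- stats::runif(n_cond) < missingRate
        }
        values[mask] <- NA_real_
    }
    list(matrix = ExprMatrix(values, exp_of),
         truth = list(clusterOf = cluster_of, archetypes = archetypes))
}

#' Simulate term annotations enriched in planted clusters
#'
#' Generates one "enriched" term per planted cluster (cycling through
#' clusters if \code{nTerms} exceeds the cluster count): the term
#' annotates a fraction \code{enrichmentFraction} of that cluster's
#' genes plus a fraction \code{backgroundRate} of all other genes.
#' Together with [simulateExpression()] this gives an end-to-end ground
#' truth for the over-representation analysis.
#'
#' @param truth The \code{truth} component returned by
#'   [simulateExpression()].
#' @param nTerms Number of terms (default: one per cluster).
#' @param enrichmentFraction Fraction of the target cluster's genes
#'   annotated (default 0.9).
#' @param backgroundRate Fraction of non-cluster genes annotated
#'   (default 0.05).
#' @param seed Integer seed.
#' @return An \linkS4class{AnnotationTable}; term ids are
#'   \code{SYN:0001} ... and term k targets cluster
#'   \code{((k - 1) mod nClusters) + 1}.
#' @export
simulateAnnotations <- function(truth, nTerms = NULL,
                                enrichmentFraction = 0.9,
                                backgroundRate = 0.05, seed = 1L) {
    if (enrichmentFraction < 0 || enrichmentFraction > 1 ||
        backgroundRate < 0 || backgroundRate > 1)
        stop("enrichmentFraction and backgroundRate must be in [0, 1]")
    cluster_of <- truth$clusterOf
    n_clusters <- max(cluster_of)
    if (is.null(nTerms)) nTerms <- n_clusters
    genes <- names(cluster_of)
    ann <- rep(list(character()), length(genes))
    names(ann) <- genes
    term_names <- character()
    for (k in seq_len(nTerms)) {
        term <- sprintf("SYN:%04d", k)
        target <- ((k - 1L) %% n_clusters) + 1L
        term_names[term] <- sprintf("planted term for cluster %d", target)
        set.seed(.splitSeed(seed, 100 + k))
        inside <- genes[cluster_of == target]
        outside <- genes[cluster_of != target]
        pick_in <- sample(inside, round(enrichmentFraction * length(inside)))
        pick_out <- if (backgroundRate > 0)
            sample(outside, round(backgroundRate * length(outside)))
        else character()
        for (g in c(pick_in, pick_out))
            ann[[g]] <- c(ann[[g]], term)
    }
    ann <- ann[lengths(ann) > 0L]
    if (!length(ann)) stop("no gene received any annotation")
    methods::new("AnnotationTable",
                 terms = lapply(ann, function(t) sort(unique(t))),
                 termNames = term_names, propagated = FALSE)
}

#' Write a simulated annotation table as two-column TSV
#'
#' @param annotations An \linkS4class{AnnotationTable}.
#' @param path Output path (gene id, term id; one pair per line).
#' @return \code{path}, invisibly.
#' @export
writeAnnotations <- function(annotations, path) {
    stopifnot(methods::is(annotations, "AnnotationTable"))
    genes <- rep(names(annotations@terms), lengths(annotations@terms))
    terms <- unlist(annotations@terms, use.names = FALSE)
    utils::write.table(data.frame(genes, terms), path, sep = "\t",
                       quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    invisible(path)
}
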