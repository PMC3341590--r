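#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' ExprMatrix: a gene x condition expression matrix with experiment grouping
#'
#' An \code{ExprMatrix} is a
#' \linkS4class{SummarizedExperiment} holding one assay named
#' \code{"exprs"} (real values, \code{NA} allowed) whose columns are
#' experimental conditions, each belonging to exactly one experiment
#' (\code{colData} column \code{"experiment"}). Values are dimensionless
#' normalized expression measures (log-ratio-like); missingness is
#' per-cell.
#'
#' Invariants enforced by the validity method: unique gene and condition
#' identifiers, at least one gene and two conditions, a non-missing
#' experiment label for every condition, and no gene missing in all
#' conditions.
#'
#' @seealso [ExprMatrix()] for construction, [readExprMatrix()] for I/O,
#'   [medianShift()] for normalization, [trainSOM()] for clustering.
#' @aliases ExprMatrix-class
#' @exportClass ExprMatrix
setClass("ExprMatrix", contains = "SummarizedExperiment")

setValidity("ExprMatrix", function(object) {
    msg <- character()
    if (!("exprs" %in% SummarizedExperiment::assayNames(object)))
        msg <- c(msg, "assay 'exprs' is required")
    if (!("experiment" %in% colnames(SummarizedExperiment::colData(object))))
        msg <- c(msg, "colData column 'experiment' is required")
    if (length(msg))
        return(msg)
    v <- SummarizedExperiment::assay(object, "exprs")
    if (is.null(rownames(v)) || is.null(colnames(v)))
        msg <- c(msg, "gene (row) and condition (column) names are required")
    else {
        if (anyDuplicated(rownames(v)))
            msg <- c(msg, "duplicate gene identifiers")
        if (anyDuplicated(colnames(v)))
            msg <- c(msg, "duplicate condition identifiers")
    }
    if (nrow(v) < 1L)
        msg <- c(msg, "at least one gene is required")
    if (ncol(v) < 2L)
        msg <- c(msg, "at least two conditions are required")
    if (!is.numeric(v))
        msg <- c(msg, "expression values must be numeric")
    ex <- SummarizedExperiment::colData(object)$experiment
    if (anyNA(ex) || !all(nzchar(as.character(ex))))
        msg <- c(msg, "every condition needs a non-empty experiment label")
    if (is.numeric(v) && nrow(v) >= 1L && ncol(v) >= 1L) {
        allmiss <- rowSums(!is.na(v)) == 0L
        if (any(allmiss))
            msg <- c(msg, paste0("gene(s) with all values missing: ",
                                 paste(head(rownames(v)[allmiss], 5L),
                                       collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
})

#' SOMConfig: training configuration for a self-organizing map
#'
#' Holds the map geometry and training schedule parameters. Defaults
#' follow the published configuration for genome-scale expression maps:
#' a 25 x 20 grid (500 nodes), starting learning rate 0.1, starting
#' neighbourhood radius 10, and on average 20 presentations of each
#' input vector. The learning rate and radius both decay linearly to
#' zero over training.
#'
#' @slot width,height Integer grid dimensions (columns, rows).
#' @slot lr0 Starting learning rate alpha0, in (0, 1].
#' @slot radius0 Starting neighbourhood radius (grid units, >= 0).
#' @slot presentationsPerGene Average number of times each gene profile
#'   is presented during training (total presentations = this x n genes).
#' @slot metric Similarity for best-matching-unit search:
#'   \code{"pearson"} (correlation over jointly observed components) or
#'   \code{"euclidean"} (negated distance over jointly observed
#'   components, normalized by the square root of the overlap size).
#' @slot seed Integer RNG seed; fixes initialization and the
#'   presentation order, hence the whole trained map.
#' @slot minOverlap Minimum number of jointly observed components for a
#'   similarity to be defined (default 3); below it the pair is
#'   "incomparable" and can never win a BMU search.
#' @slot gridMetric Grid distance used for the update neighbourhood:
#'   \code{"cityblock"} (default, consistent with the spatial test) or
#'   \code{"chebyshev"}.
#' @slot kernel Neighbourhood kernel: \code{"bubble"} (flat update at
#'   full learning rate for all nodes within the radius; default) or
#'   \code{"gaussian"} (learning rate decays with grid distance).
#' @aliases SOMConfig-class
#' @seealso [SOMConfig()], [trainSOM()]
#' @exportClass SOMConfig
setClass("SOMConfig",
    representation(width = "integer", height = "integer",
                   lr0 = "numeric", radius0 = "numeric",
                   presentationsPerGene = "numeric",
                   metric = "character", seed = "integer",
                   minOverlap = "integer", gridMetric = "character",
                   kernel = "character"))

setValidity("SOMConfig", function(object) {
    msg <- character()
    if (object@width < 1L || object@height < 1L)
        msg <- c(msg, "width and height must be >= 1")
    if (!(object@lr0 > 0 && object@lr0 <= 1))
        msg <- c(msg, "lr0 must be in (0, 1]")
    if (object@radius0 < 0)
        msg <- c(msg, "radius0 must be >= 0")
    if (object@presentationsPerGene < 1)
        msg <- c(msg, "presentationsPerGene must be >= 1")
    if (!(object@metric %in% c("pearson", "euclidean")))
        msg <- c(msg, "metric must be 'pearson' or 'euclidean'")
    if (object@minOverlap < 2L)
        msg <- c(msg, "minOverlap must be >= 2")
    if (!(object@gridMetric %in% c("cityblock", "chebyshev")))
        msg <- c(msg, "gridMetric must be 'cityblock' or 'chebyshev'")
    if (!(object@kernel %in% c("bubble", "gaussian")))
        msg <- c(msg, "kernel must be 'bubble' or 'gaussian'")
    if (length(msg)) msg else TRUE
})

#' SOMMap: a trained self-organizing map of expression profiles
#'
#' Couples the grid of node ("codebook") vectors with the final
#' assignment of every gene to its best-matching node. Node coordinates
#' are 0-based: \code{x} is the column (0..width-1) and \code{y} the row
#' (0..height-1). Each node vector has one component per condition and
#' is interpretable as the mean expression profile of the genes mapping
#' there.
#'
#' @slot config The \linkS4class{SOMConfig} used for training.
#' @slot codebook Numeric matrix, one row per node in row-major order
#'   (node index = y * width + x), one column per condition.
#' @slot conditionIds Character vector of condition identifiers.
#' @slot assignment \code{data.frame} with columns \code{gene},
#'   \code{x}, \code{y}: the final gene-to-node assignment.
#' @aliases SOMMap-class
#' @seealso [trainSOM()], [assignGenes()], [nodeSummary()],
#'   [writeSOMMap()]
#' @exportClass SOMMap
setClass("SOMMap",
    representation(config = "SOMConfig", codebook = "matrix",
                   conditionIds = "character", assignment = "data.frame"))

setValidity("SOMMap", function(object) {
    msg <- character()
    cfg <- object@config
    if (nrow(object@codebook) != cfg@width * cfg@height)
        msg <- c(msg, "codebook must have width * height rows")
    if (ncol(object@codebook) != length(object@conditionIds))
        msg <- c(msg, "node vectors must have one component per condition")
    a <- object@assignment
    if (!all(c("gene", "x", "y") %in% colnames(a)))
        msg <- c(msg, "assignment needs columns gene, x, y")
    else {
        if (anyDuplicated(a$gene))
            msg <- c(msg, "each gene must be assigned to exactly one node")
        if (nrow(a) && (any(a$x < 0L) || any(a$x >= cfg@width) ||
                        any(a$y < 0L) || any(a$y >= cfg@height)))
            msg <- c(msg, "assigned coordinates out of the grid")
    }
    if (length(msg)) msg else TRUE
})

#' AnnotationTable: gene-to-term annotations
#'
#' Maps gene identifiers to sets of ontology term identifiers (for
#' example GO accessions), optionally closed under ancestor propagation
#' along \code{is_a}/\code{part_of} relations.
#'
#' @slot terms Named list; one character vector of term ids per gene.
#'   Every gene maps to a non-empty set.
#' @slot termNames Optional named character vector of term descriptions.
#' @slot propagated Logical; \code{TRUE} after
#'   [propagateAnnotations()] has closed every gene's term set under
#'   ancestor traversal.
#' @aliases AnnotationTable-class
#' @seealso [readAnnotations()], [propagateAnnotations()],
#'   [runEnrichment()]
#' @exportClass AnnotationTable
setClass("AnnotationTable",
    representation(terms = "list", termNames = "character",
                   propagated = "logical"))

setValidity("AnnotationTable", function(object) {
    msg <- character()
    if (is.null(names(object@terms)) || anyDuplicated(names(object@terms)))
        msg <- c(msg, "terms must be a uniquely named list (one entry per gene)")
    if (any(lengths(object@terms) == 0L))
        msg <- c(msg, "every gene must map to a non-empty term set")
    if (length(object@propagated) != 1L)
        msg <- c(msg, "propagated must be a single logical")
    if (length(msg)) msg else TRUE
})

#' GeneSet: a named set of gene identifiers
#'
#' @slot name Set label.
#' @slot members Character vector of unique gene identifiers
#'   (non-empty).
#' @aliases GeneSet-class
#' @seealso [readGeneSets()], [nonrandomTest()], [overlayCounts()]
#' @exportClass GeneSet
setClass("GeneSet",
    representation(name = "character", members = "character"))

setValidity("GeneSet", function(object) {
    msg <- character()
    if (length(object@name) != 1L || !nzchar(object@name))
        msg <- c(msg, "name must be a single non-empty string")
    if (length(object@members) == 0L)
        msg <- c(msg, "members must be non-empty")
    if (anyDuplicated(object@members))
        msg <- c(msg, "members must be unique")
    if (length(msg)) msg else TRUE
})

#' EnrichmentResults: per-(node, term) over-representation results
#'
#' One row per (occupied node, tested term) pair, with hypergeometric
#' contingency counts, the upper-tail Fisher probability, the
#' Benjamini-Hochberg adjusted value (pooled over all performed tests)
#' and the reporting flag (\code{fdr <= threshold} and at least 4
#' annotated genes in the node).
#'
#' @slot table \code{data.frame} with columns \code{x}, \code{y},
#'   \code{term}, \code{k}, \code{K}, \code{n}, \code{N}, \code{p_raw},
#'   \code{fdr}, \code{reported}.
#' @slot nTests Number of (node, term) tests performed; the BH family
#'   size.
#' @slot fdrThreshold Threshold used for the \code{reported} flag.
#' @slot termSignature Named character vector mapping each tested term
#'   to a signature of its annotated mapped-gene set, used for
#'   redundancy collapse when counting distinct enriched terms.
#' @aliases EnrichmentResults-class
#' @seealso [runEnrichment()], [countEnrichedTerms()]
#' @exportClass EnrichmentResults
setClass("EnrichmentResults",
    representation(table = "data.frame", nTests = "integer",
                   fdrThreshold = "numeric", termSignature = "character"))

#' SpatialTestResult: empirical non-randomness test for one gene set
#'
#' @slot setName Gene-set label.
#' @slot n Size of the tested set after intersection with the mapped
#'   genes.
#' @slot dObserved Observed mean city-block distance of each member to
#'   its closest within-set neighbour.
#' @slot nSamples Number of null samples drawn.
#' @slot countLower Number of null samples with d' strictly below the
#'   observed d.
#' @slot pRaw \code{countLower / nSamples}.
#' @slot pCorrected Bonferroni-corrected value,
#'   \code{min(1, pRaw * nTests)}.
#' @slot pConservative Add-one estimate
#'   \code{(countLower + 1) / (nSamples + 1)}; an extension beyond the
#'   plain sampling estimate, reported because \code{pRaw} can be
#'   exactly zero.
#' @slot nTests Number of tests the Bonferroni factor accounts for.
#' @aliases SpatialTestResult-class
#' @seealso [nonrandomTest()]
#' @exportClass SpatialTestResult
setClass("SpatialTestResult",
    representation(setName = "character", n = "integer",
                   dObserved = "numeric", nSamples = "integer",
                   countLower = "integer", pRaw = "numeric",
                   pCorrected = "numeric", pConservative = "numeric",
                   nTests = "integer"))

#' ReproducibilityResult: co-clustering stability across re-seeded maps
#'
#' @slot nPairs Number of sampled co-clustered gene pairs.
#' @slot nSame Pairs assigned to identical nodes on the alternate map.
#' @slot nNear Pairs re-mapping within \code{nearRadius} grid units
#'   (city-block) on the alternate map.
#' @slot fracSame,fracNear The corresponding fractions.
#' @slot nearRadius Grid distance defining "nearby" (default 5).
#' @aliases ReproducibilityResult-class
#' @seealso [coclusterReproducibility()]
#' @exportClass ReproducibilityResult
setClass("ReproducibilityResult",
    representation(nPairs = "integer", nSame = "integer",
                   nNear = "integer", fracSame = "numeric",
                   fracNear = "numeric", nearRadius = "integer"))

setValidity("ReproducibilityResult", function(object) {
    msg <- character()
    if (object@nSame > object@nNear)
        msg <- c(msg, "nSame cannot exceed nNear")
    if (object@nNear > object@nPairs)
        msg <- c(msg, "nNear cannot exceed nPairs")
    fr <- c(object@fracSame, object@fracNear)
    if (any(fr < 0) || any(fr > 1))
        msg <- c(msg, "fractions must be in [0, 1]")
    if (length(msg)) msg else TRUE
})
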