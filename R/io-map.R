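.MAP_FORMAT <- "exprSOM-map"
.MAP_VERSION <- "1.0"

#' Serialize a trained map to JSON (and optionally a flat TSV)
#'
#' The JSON document is versioned and self-contained: training
#' configuration, condition ids, the codebook (one row per node,
#' row-major with node index = y * width + x) and the gene assignment.
#' Node vectors are written with 17 significant digits so that
#' [readSOMMap()] reproduces them to full double precision. The optional
#' TSV export holds one row per gene: \code{gene}, \code{x}, \code{y}
#' (0-based node coordinates).
#'
#' @param map A \linkS4class{SOMMap}.
#' @param path Output JSON path.
#' @param tsvPath Optional output path for the flat assignment TSV.
#' @return \code{path}, invisibly.
#' @export
writeSOMMap <- function(map, path, tsvPath = NULL) {
    stopifnot(methods::is(map, "SOMMap"))
    cfg <- map@config
    doc <- list(
        format = .MAP_FORMAT,
        version = .MAP_VERSION,
        config = list(width = cfg@width, height = cfg@height,
                      lr0 = cfg@lr0, radius0 = cfg@radius0,
                      presentationsPerGene = cfg@presentationsPerGene,
                      metric = cfg@metric, seed = cfg@seed,
                      minOverlap = cfg@minOverlap,
                      gridMetric = cfg@gridMetric, kernel = cfg@kernel),
        condition_ids = map@conditionIds,
        codebook = unname(apply(map@codebook, 1L, identity,
                                simplify = FALSE)),
        assignment = list(gene = map@assignment$gene,
                          x = map@assignment$x, y = map@assignment$y))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                         null = "null")
    if (!is.null(tsvPath))
        exportAssignments(map, tsvPath)
    invisible(path)
}

#' Export the gene-to-node assignment as TSV
#'
#' @param map A \linkS4class{SOMMap}.
#' @param path Output TSV path (columns \code{gene}, \code{x},
#'   \code{y}).
#' @param header Optional comment lines (written with a leading
#'   \code{#}).
#' @return \code{path}, invisibly.
#' @export
exportAssignments <- function(map, path, header = NULL) {
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(header)) writeLines(paste0("# ", header), con)
    writeLines("gene\tx\ty", con)
    a <- map@assignment
    writeLines(paste(a$gene, a$x, a$y, sep = "\t"), con)
    invisible(path)
}

#' Read a serialized map
#'
#' @param path JSON path written by [writeSOMMap()].
#' @return A \linkS4class{SOMMap}; node vectors are recovered to full
#'   double precision and assignments exactly.
#' @export
readSOMMap <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                    error = function(e)
                        stop("format error: not valid map JSON (",
                             conditionMessage(e), ")", call. = FALSE))
    if (!identical(doc$format, .MAP_FORMAT))
        stop("format error: not an ", .MAP_FORMAT, " document")
    if (!identical(doc$version, .MAP_VERSION))
        stop("format error: unsupported map version '", doc$version,
             "' (expected ", .MAP_VERSION, ")")
    cf <- doc$config
    cfg <- SOMConfig(width = cf$width, height = cf$height, lr0 = cf$lr0,
                     radius0 = cf$radius0,
                     presentationsPerGene = cf$presentationsPerGene,
                     metric = cf$metric, seed = cf$seed,
                     minOverlap = cf$minOverlap, gridMetric = cf$gridMetric,
                     kernel = cf$kernel)
    codebook <- doc$codebook
    if (is.list(codebook))
        codebook <- do.call(rbind, codebook)
    assignment <- data.frame(gene = as.character(doc$assignment$gene),
                             x = as.integer(doc$assignment$x),
                             y = as.integer(doc$assignment$y),
                             stringsAsFactors = FALSE)
    methods::new("SOMMap", config = cfg, codebook = codebook,
                 conditionIds = as.character(doc$condition_ids),
                 assignment = assignment)
}
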