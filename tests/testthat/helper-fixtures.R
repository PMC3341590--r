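## Shared fixture builders. Everything is generated in code under fixed
## seeds; the heavier trained map is memoized so several test files can
## reuse it without retraining.

.fixtures <- new.env(parent = emptyenv())

## Default-condition synthetic compendium: 2000 genes, 4 experiment
## blocks totalling 20 conditions, 10 planted clusters.
sharedSim <- function() {
    if (is.null(.fixtures$sim))
        .fixtures$sim <- simulateExpression(seed = 101L)
    .fixtures$sim
}

sharedMap <- function() {
    if (is.null(.fixtures$map))
        .fixtures$map <- trainSOM(sharedSim()$matrix,
                                  SOMConfig(width = 15L, height = 10L,
                                            seed = 101L))
    .fixtures$map
}

## Small ExprMatrix from a literal matrix; one experiment unless given.
quickMatrix <- function(values, experiments = NULL) {
    if (is.null(experiments))
        experiments <- stats::setNames(rep("e1", ncol(values)),
                                       colnames(values))
    ExprMatrix(values, experiments)
}

## A map built by hand (no training): genes placed at given coordinates.
manualMap <- function(width, height, genes, x, y, codebook = NULL,
                      conditions = c("c1", "c2", "c3")) {
    if (is.null(codebook))
        codebook <- matrix(seq_len(width * height * length(conditions)),
                           width * height, length(conditions))
    colnames(codebook) <- conditions
    new("SOMMap",
        config = SOMConfig(width = width, height = height),
        codebook = codebook, conditionIds = conditions,
        assignment = data.frame(gene = genes, x = as.integer(x),
                                y = as.integer(y),
                                stringsAsFactors = FALSE))
}

## Same map with gene labels shuffled (a seeded random re-assignment).
permuteMap <- function(map, seed) {
    set.seed(seed)
    a <- assignment(map)
    a$gene <- sample(a$gene)
    new("SOMMap", config = map@config, codebook = map@codebook,
        conditionIds = conditionIds(map), assignment = a)
}

## Independent oracle for the upper-tail hypergeometric probability:
## brute-force tail sum of PMF terms built from lchoose (all terms
## positive, so the sum carries no cancellation).
bruteFisherTail <- function(k, K, n, N) {
    i <- k:min(n, K)
    sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

## Annotation table from a named list gene -> terms.
annotationsFromList <- function(lst) {
    new("AnnotationTable", terms = lapply(lst, function(t) sort(unique(t))),
        termNames = character(), propagated = FALSE)
}

## Chance probability that a uniformly random gene pair co-clusters on
## `map` (occupancy-based closed form): sum_j c_j (c_j - 1) / (G (G - 1)).
chanceCoclusterProb <- function(map) {
    counts <- nodeSummary(map)$count
    g <- sum(counts)
    sum(counts * (counts - 1)) / (g * (g - 1))
}
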