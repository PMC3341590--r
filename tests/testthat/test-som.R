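test_that("pairwise similarity matches hand-expanded correlation", {
    expect_equal(similarity(c(1, 2, 3), c(1, 2, 3)), 1)
    expect_equal(similarity(c(1, 2, 3), c(1, 2, 4)), 9 / sqrt(84))
    ## missing components are excluded pairwise
    expect_equal(similarity(c(1, NA, 3, 4), c(0, 7, 2, 3)),
                 cor(c(1, 3, 4), c(0, 2, 3)))
    ## incomparable: small overlap or zero variance
    expect_identical(similarity(c(1, NA, NA, 4), c(0, 7, 2, 3)), -Inf)
    expect_identical(similarity(c(2, 2, 2), c(1, 2, 3)), -Inf)
    ## euclidean: negated distance normalized by sqrt(overlap)
    expect_equal(similarity(c(0, 0, 0, 0), c(1, 1, 1, 1), "euclidean"), -1)
    expect_equal(similarity(c(0, NA, 0), c(3, 9, 4), "euclidean",
                            minOverlap = 2L), -sqrt(25 / 2))
    ## default minOverlap = 3 leaves a 2-component overlap incomparable
    expect_identical(similarity(c(0, NA, 0), c(3, 9, 4), "euclidean"),
                     -Inf)
})

test_that("node-wise similarity agrees with the pairwise definition", {
    set.seed(5)
    codebook <- matrix(rnorm(40), 8L, 5L)
    x <- c(0.3, NA, -1, 2, 0.5)
    sims <- exprSOM:::.simToNodes(x, codebook, "pearson", 3L)
    for (i in 1:8)
        expect_equal(sims[i], similarity(x, codebook[i, ]))
    simE <- exprSOM:::.simToNodes(x, codebook, "euclidean", 3L)
    for (i in 1:8)
        expect_equal(simE[i], similarity(x, codebook[i, ], "euclidean"))
    ## constant node row loses every contest under pearson
    codebook[3L, ] <- 2
    expect_identical(
        exprSOM:::.simToNodes(x, codebook, "pearson", 3L)[3L], -Inf)
})

test_that("map initialization stays in the data range and follows the seed", {
    sim <- simulateExpression(nGenes = 60L,
                              experimentBlocks = c(eA = 4L, eB = 4L),
                              nClusters = 3L, seed = 11L)
    cfg <- SOMConfig(width = 6L, height = 5L, seed = 3L)
    m1 <- initMap(cfg, sim$matrix)
    v <- exprValues(sim$matrix)
    lo <- apply(v, 2L, min, na.rm = TRUE)
    hi <- apply(v, 2L, max, na.rm = TRUE)
    cb <- nodeVectors(m1)
    for (j in seq_len(ncol(cb))) {
        expect_true(all(cb[, j] >= lo[j]))
        expect_true(all(cb[, j] <= hi[j]))
    }
    expect_identical(nodeVectors(initMap(cfg, sim$matrix)), cb)
    for (s in 1:10) {
        other <- initMap(SOMConfig(width = 6L, height = 5L,
                                   seed = 100L + s), sim$matrix)
        expect_gt(sum(nodeVectors(other) != cb), 0L)
    }
})

test_that("the decay schedule is linear and reaches zero at t = T", {
    total <- 400L
    t <- c(0L, 100L, 200L, 399L, 400L)
    sched <- vapply(t, exprSOM:::.schedule, numeric(2L), total = total,
                    lr0 = 0.1, radius0 = 10)
    expect_equal(sched["alpha", ], 0.1 * (1 - t / total))
    expect_equal(sched["radius", ], 10 * (1 - t / total))
    expect_true(all(diff(sched["alpha", ]) < 0))
    expect_identical(sched[, 5L], c(alpha = 0, radius = 0))
})

test_that("a 1x1 map contracts onto a single gene profile", {
    v <- matrix(c(2, -1, 0.5, 3, -2), 1L,
                dimnames = list("g1", paste0("c", 1:5)))
    em <- quickMatrix(v)
    cfg <- SOMConfig(width = 1L, height = 1L, lr0 = 0.1, radius0 = 0,
                     presentationsPerGene = 200, seed = 9L)
    map <- trainSOM(em, cfg)
    ## numeric oracle: iterate the scalar contraction w <- w + a(t)(x - w)
    ## from the same random initialization
    w <- nodeVectors(initMap(cfg, em))[1L, ]
    total <- 200L
    for (t in seq_len(total)) {
        a <- 0.1 * (1 - (t - 1) / total)
        w <- w + a * (v[1L, ] - w)
    }
    expect_equal(unname(nodeVectors(map)[1L, ]), unname(w),
                 tolerance = 1e-12)
    expect_true(all(abs(nodeVectors(map)[1L, ] - v[1L, ]) < 1e-3))
})

test_that("missing input components never update node components", {
    set.seed(33)
    cfg <- SOMConfig(width = 4L, height = 3L)
    coords <- exprSOM:::.gridCoords(cfg)
    codebook <- matrix(rnorm(12L * 5L), 12L, 5L)
    xg <- c(1, NA, 3, NA, 4)
    upd <- exprSOM:::.somUpdate(codebook, coords, bmu = 6L, xg = xg,
                                alpha = 0.2, radius = 2,
                                gridMetric = "cityblock",
                                kernel = "bubble")
    ## missing components untouched everywhere
    expect_identical(upd[, c(2L, 4L)], codebook[, c(2L, 4L)])
    ## nodes outside the radius untouched entirely
    d <- exprSOM:::.gridDist(coords, coords[6L, ], "cityblock")
    far <- d > 2
    expect_identical(upd[far, ], codebook[far, ])
    ## neighbours move by the update rule on observed components
    nb <- which(!far)
    for (i in nb)
        expect_equal(upd[i, c(1L, 3L, 5L)],
                     codebook[i, c(1L, 3L, 5L)] +
                         0.2 * (xg[c(1L, 3L, 5L)] -
                                codebook[i, c(1L, 3L, 5L)]))
})

test_that("one update moves a node towards, never past, the input", {
    v <- matrix(c(1, 1, 2), 1L, dimnames = list("g1", paste0("c", 1:3)))
    em <- quickMatrix(v)
    cfg <- SOMConfig(width = 1L, height = 1L, lr0 = 0.1, radius0 = 0,
                     presentationsPerGene = 1, seed = 4L)
    w0 <- nodeVectors(initMap(cfg, em))[1L, ]
    w1 <- nodeVectors(trainSOM(em, cfg))[1L, ]
    expect_equal(unname(w1), unname(w0 + 0.1 * (v[1L, ] - w0)))
    between <- (w1 - w0) * (v[1L, ] - w1) >= -1e-12
    expect_true(all(between))
})

test_that("training is deterministic and conserves genes", {
    sim <- simulateExpression(nGenes = 120L,
                              experimentBlocks = c(eA = 5L, eB = 5L),
                              nClusters = 4L, seed = 21L)
    cfg <- SOMConfig(width = 6L, height = 5L, presentationsPerGene = 10,
                     seed = 21L)
    m1 <- trainSOM(sim$matrix, cfg)
    m2 <- trainSOM(sim$matrix, cfg)
    expect_identical(nodeVectors(m1), nodeVectors(m2))
    expect_identical(assignment(m1), assignment(m2))
    summ <- nodeSummary(m1)
    expect_identical(nrow(summ), 30L)  # empty nodes listed too
    expect_identical(sum(summ$count), 120L)
})

test_that("assignment is an argmax with a deterministic tie-break", {
    set.seed(8)
    codebook <- matrix(rnorm(24L * 3L), 24L, 3L)
    map <- manualMap(6L, 4L, character(), integer(), integer(),
                     codebook = codebook)
    ## a gene equal to the node vector at (3, 2) lands there
    target <- 2L * 6L + 3L + 1L
    v <- matrix(codebook[target, ], 1L,
                dimnames = list("g1", c("c1", "c2", "c3")))
    a <- assignment(assignGenes(quickMatrix(v), map))
    expect_identical(c(a$x, a$y), c(3L, 2L))
    ## identical profiles receive identical nodes
    v2 <- matrix(rep(c(0.4, -1, 2), each = 2L), 2L, byrow = FALSE,
                 dimnames = list(c("ga", "gb"), c("c1", "c2", "c3")))
    v2["gb", ] <- v2["ga", ]
    a2 <- assignment(assignGenes(quickMatrix(v2), map))
    expect_identical(c(a2$x[1L], a2$y[1L]), c(a2$x[2L], a2$y[2L]))
    ## all-equal node vectors: tie broken to smallest (y, x) = (0, 0)
    flat <- manualMap(6L, 4L, character(), integer(), integer(),
                      codebook = matrix(rep(c(1, 2, 3), each = 24L),
                                        24L, 3L))
    a3 <- assignment(assignGenes(quickMatrix(v), flat))
    expect_identical(c(a3$x, a3$y), c(0L, 0L))
    ## a gene incomparable to every node is a hard error naming it
    vna <- matrix(c(1, NA, NA), 1L,
                  dimnames = list("gene_bad", c("c1", "c2", "c3")))
    vok <- matrix(c(1, 0, 2), 1L,
                  dimnames = list("gok", c("c1", "c2", "c3")))
    em2 <- quickMatrix(rbind(vna, vok))
    expect_error(assignGenes(em2, map), "gene_bad")
})

test_that("genes from a planted profile land close together on the map", {
    sim <- simulateExpression(nGenes = 200L,
                              experimentBlocks = c(eA = 6L, eB = 6L),
                              nClusters = 4L, noiseSd = 0.1,
                              missingRate = 0, seed = 31L)
    ## four well-separated profiles comfortably fit a 6 x 5 grid; each
    ## planted profile should occupy one compact blob
    map <- trainSOM(sim$matrix,
                    SOMConfig(width = 6L, height = 5L, seed = 31L))
    a <- assignment(map)
    cl <- sim$truth$clusterOf[a$gene]
    near <- 0L; tot <- 0L
    for (k in 1:4) {
        pos <- a[cl == k, c("x", "y")]
        dx <- abs(outer(pos$x, pos$x, "-"))
        dy <- abs(outer(pos$y, pos$y, "-"))
        d <- (dx + dy)[upper.tri(dx)]
        near <- near + sum(d <= 3L)
        tot <- tot + length(d)
    }
    expect_gt(near / tot, 0.9)
})

test_that("planted clusters are tighter than the between-cluster spread", {
    for (k in c(4L, 10L)) {
        for (s in 1:5) {
            sim <- simulateExpression(
                nGenes = 300L,
                experimentBlocks = c(eA = 6L, eB = 6L),
                nClusters = k, seed = 400L + 10L * k + s)
            map <- trainSOM(sim$matrix,
                            SOMConfig(width = 10L, height = 8L,
                                      presentationsPerGene = 10,
                                      seed = 400L + 10L * k + s))
            a <- assignment(map)
            cl <- sim$truth$clusterOf[a$gene]
            dx <- abs(outer(a$x, a$x, "-"))
            dy <- abs(outer(a$y, a$y, "-"))
            d <- dx + dy
            same <- outer(cl, cl, "==") & upper.tri(d)
            diff <- (!outer(cl, cl, "==")) & upper.tri(d)
            expect_lt(mean(d[same]), mean(d[diff]))
        }
    }
})

test_that("co-clustered pairs re-map near each other above chance", {
    sim <- simulateExpression(nGenes = 400L,
                              experimentBlocks = c(eA = 6L, eB = 6L),
                              nClusters = 8L, seed = 51L)
    maps <- lapply(1:5, function(s)
        trainSOM(sim$matrix, SOMConfig(width = 10L, height = 8L,
                                       presentationsPerGene = 10,
                                       seed = 50L + s)))
    main <- maps[[1L]]
    rep_real <- coclusterReproducibility(main, maps[-1L],
                                         nPairs = 4000L, seed = 7L)
    ## chance level: the same sampling against seeded label permutations
    perm <- lapply(2:5, function(s) permuteMap(maps[[s]], 900L + s))
    rep_perm <- coclusterReproducibility(main, perm, nPairs = 4000L,
                                         seed = 7L)
    expect_gt(rep_real@fracNear, rep_perm@fracNear)
    expect_gt(rep_real@fracSame, rep_perm@fracSame)
})
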