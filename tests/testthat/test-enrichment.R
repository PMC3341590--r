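test_that("term frequency filter applies the strict boundary rules", {
    genes <- sprintf("g%03d", 1:100)
    make_ann <- function(K) annotationsFromList(
        setNames(rep(list("GO:T"), K), genes[seq_len(K)]))
    expect_identical(filterTerms(make_ann(9L), genes), character())
    expect_identical(filterTerms(make_ann(10L), genes), "GO:T")
    expect_identical(filterTerms(make_ann(25L), genes), "GO:T")  # = N/4
    expect_identical(filterTerms(make_ann(26L), genes), character())
    ## only mapped genes count towards K: 10 of the 26 annotated genes
    ## are on this map of 100 genes, so the term is kept
    ann <- make_ann(26L)
    mapped <- c(genes[1:10], sprintf("h%03d", 1:90))
    expect_identical(filterTerms(ann, mapped), "GO:T")
})

test_that("upper-tail Fisher probability matches the brute-force tail sum", {
    expect_identical(fisherUpperTail(0, 20, 10, 100), 1)
    expect_identical(fisherUpperTail(5, 5, 5, 5), 1)  # forced configuration
    ## frozen value from the exact tail-sum oracle
    expect_equal(fisherUpperTail(5, 20, 10, 100), 2.546454642704320e-02,
                 tolerance = 1e-12)
    expect_equal(fisherUpperTail(5, 20, 10, 100),
                 bruteFisherTail(5, 20, 10, 100), tolerance = 1e-12)
    ## spot sweep against the oracle (the exhaustive N <= 60 sweep runs
    ## with the acceptance checks)
    set.seed(13)
    for (rep in 1:200) {
        N <- sample(2:60, 1L)
        K <- sample.int(N, 1L)
        n <- sample.int(N, 1L)
        ks <- max(0L, n + K - N):min(n, K)
        k <- ks[sample.int(length(ks), 1L)]
        expect_equal(fisherUpperTail(k, K, n, N),
                     bruteFisherTail(k, K, n, N),
                     tolerance = 1e-10)
    }
    expect_error(fisherUpperTail(6, 5, 10, 100), "exceed")
    expect_error(fisherUpperTail(0, 10, 10, 15), "minimum attainable")
})

test_that("BH step-up adjustment reproduces hand-derived values", {
    expect_identical(bhFDR(0.03, m = 1L), 0.03)
    expect_equal(bhFDR(c(0.01, 0.04)), c(0.02, 0.04))
    expect_equal(bhFDR(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4L))
    ## family larger than the vector scales the numerator
    expect_equal(bhFDR(c(0.01, 0.04), m = 4L), c(0.04, 0.08))
    ## monotone when input sorted ascending; never below min(p)
    set.seed(3)
    p <- sort(runif(50))
    q <- bhFDR(p)
    expect_true(all(diff(q) >= -1e-15))
    expect_true(all(q >= min(p) - 1e-15))
    expect_error(bhFDR(c(0.5, 1.2)), "\\[0, 1\\]")
    expect_error(bhFDR(c(0.1, 0.2), m = 1L), "at least")
})

test_that("a term confined to one node is reported with a tiny p", {
    genes <- sprintf("g%03d", 1:500)
    set.seed(77)
    x <- sample(0:9, 500L, replace = TRUE)
    y <- sample(0:7, 500L, replace = TRUE)
    ## put the 20 term genes together in one node
    x[1:20] <- 4L; y[1:20] <- 3L
    map <- manualMap(10L, 8L, genes, x, y)
    ann <- annotationsFromList(c(
        setNames(rep(list("GO:X"), 20L), genes[1:20]),
        setNames(rep(list("GO:BG"), 60L), genes[101:160])))
    res <- runEnrichment(map, ann, fdrThreshold = 0.05)
    hit <- res@table[res@table$term == "GO:X" & res@table$x == 4L &
                     res@table$y == 3L, ]
    expect_identical(hit$k, 20L)
    expect_identical(hit$K, 20L)
    expect_lt(hit$p_raw, 1e-12)
    expect_true(hit$reported)
    ## counting conservation: per term, node counts sum to K
    for (t in unique(res@table$term)) {
        sub <- res@table[res@table$term == t, ]
        expect_identical(sum(sub$k), sub$K[1L])
    }
})

test_that("fewer than four annotated genes in a node blocks reporting", {
    genes <- sprintf("g%03d", 1:300)
    x <- rep(0:9, length.out = 300L)
    y <- rep(0:5, each = 50L)[1:300]
    ## 10 genes with the term; 3 of them isolated in their own node
    x[1:3] <- 9L; y[1:3] <- 5L
    map <- manualMap(10L, 6L, genes, x, y)
    ann <- annotationsFromList(setNames(rep(list("GO:Y"), 10L),
                                        genes[1:10]))
    res <- runEnrichment(map, ann, fdrThreshold = 0.5)
    hit <- res@table[res@table$x == 9L & res@table$y == 5L &
                     res@table$term == "GO:Y", ]
    expect_identical(hit$k, 3L)
    expect_lt(hit$fdr, 0.5)
    expect_false(hit$reported)
})

test_that("random annotations yield no reported term at stringent FDR", {
    map <- sharedMap()
    genes <- geneIds(map)
    for (s in 1:5) {
        set.seed(600L + s)
        ann <- annotationsFromList(setNames(
            lapply(seq_along(genes), function(i)
                paste0("GO:R", sample.int(20L, 2L))),
            genes))
        res <- runEnrichment(map, ann, fdrThreshold = 1e-6)
        expect_identical(sum(res@table$reported), 0L)
    }
})

test_that("raw p-values are calibrated under random annotation", {
    map <- sharedMap()
    genes <- geneIds(map)
    set.seed(888)
    ann <- annotationsFromList(setNames(
        lapply(seq_along(genes), function(i)
            paste0("GO:C", sample.int(60L, 3L))),
        genes))
    res <- runEnrichment(map, ann)
    frac <- mean(res@table$p_raw < 0.05)
    expect_gte(frac, 0.02)
    expect_lte(frac, 0.09)
})

test_that("distinct enriched terms collapse redundant gene sets", {
    genes <- sprintf("g%03d", 1:500)
    set.seed(55)
    x <- sample(0:9, 500L, replace = TRUE)
    y <- sample(0:7, 500L, replace = TRUE)
    ## two planted nodes, one term each; terms A and B annotate exactly
    ## the same genes
    x[1:15] <- 2L; y[1:15] <- 2L
    x[16:30] <- 7L; y[16:30] <- 5L
    map <- manualMap(10L, 8L, genes, x, y)
    ann <- annotationsFromList(c(
        setNames(rep(list(c("GO:A", "GO:B")), 15L), genes[1:15]),
        setNames(rep(list("GO:C"), 15L), genes[16:30]),
        setNames(rep(list("GO:BG"), 80L), genes[101:180])))
    res <- runEnrichment(map, ann, fdrThreshold = 0.01)
    reported <- unique(res@table$term[res@table$reported])
    expect_setequal(reported, c("GO:A", "GO:B", "GO:C"))
    counts <- countEnrichedTerms(res, c(0.01, 1e-30))
    expect_identical(unname(counts[1L]), 2L)  # A/B collapse to one
    expect_identical(unname(counts[2L]), 0L)
    ## a term reported at two nodes still counts once
    x2 <- x; y2 <- y
    x2[8:15] <- 3L  # split term A/B genes over two nodes
    map2 <- manualMap(10L, 8L, genes, x2, y2)
    res2 <- runEnrichment(map2, ann, fdrThreshold = 0.05)
    nodes_a <- res2@table[res2@table$term == "GO:A" & res2@table$reported, ]
    expect_gte(nrow(nodes_a), 2L)
    expect_identical(unname(countEnrichedTerms(res2, 0.05)), 2L)
})
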