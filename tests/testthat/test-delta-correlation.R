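test_that("spearmanPair matches hand-computed and degenerate cases", {
    ## strictly monotone relation
    res <- spearmanPair(1:8, (1:8)^3)
    expect_equal(res$rho, 1)
    expect_equal(res$p, 0)
    ## rank by hand: ranks equal the values; Pearson on ranks =
    ## (53 - 5*3*3) / 10 = 0.8
    res <- spearmanPair(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
    expect_equal(res$rho, 0.8)
    ## zero rank variance is untestable
    res <- spearmanPair(rep(3, 10), rnorm(10))
    expect_true(res$untestable)
    expect_true(is.na(res$rho))
    ## below the minimum n
    expect_true(spearmanPair(c(1, 2, NA), c(1, 2, 3))$untestable)
})

test_that("spearmanPair equals the rank-then-Pearson oracle and is monotone-invariant", {
    set.seed(21)
    for (i in 1:50) {
        n <- sample(10:60, 1)
        x <- sample(1:15, n, replace = TRUE)   # guarantees ties
        y <- x + rnorm(n, 0, 3)
        got <- spearmanPair(x, y)
        exp <- bruteSpearman(x, y)
        expect_lt(abs(got$rho - exp$rho), 1e-12)
        expect_lt(abs(got$p - exp$p), 1e-12)
        ## invariance under strictly monotone transforms
        tx <- spearmanPair(exp(x / 4), y)
        expect_lt(abs(tx$rho - got$rho), 1e-12)
        expect_lt(abs(spearmanPair(x, y)$rho -
                      spearmanPair(y, x)$rho), 1e-12)
    }
})

test_that("bhAdjust implements the step-up procedure", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
    expect_equal(bhAdjust(0.2), 0.2)
    expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
    expect_error(bhAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
    set.seed(22)
    for (i in 1:20) {
        p <- runif(sample(1:40, 1))
        expect_equal(bhAdjust(p), bruteBH(p))
    }
})

test_that("correlateAll enumerates unordered testable pairs with a correct family", {
    set.seed(23)
    X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("A", "B", "C")))
    e <- correlateAll(X, min_n = 10)
    expect_equal(nrow(e), 3L)                       # C(3,2)
    expect_true(all(e$biomarker_a < e$biomarker_b))
    expect_equal(e$q, bruteBH(e$p))
    ## one pair below min_n: 5 biomarkers -> 9 tested, family size 9
    X <- matrix(rnorm(40 * 5), 40, 5,
                dimnames = list(NULL, LETTERS[1:5]))
    X[1:28, "A"] <- NA        # A observed on 29:40 only
    X[33:40, "B"] <- NA       # B observed on 1:32: A&B share 4 < min_n
    e <- correlateAll(X, min_n = 10)
    expect_equal(nrow(e), 9L)
    un <- attr(e, "untested")
    expect_equal(nrow(un), 1L)
    expect_equal(c(un$biomarker_a, un$biomarker_b), c("A", "B"))
    expect_equal(e$q, bruteBH(e$p))                 # BH over exactly 9
})

test_that("correlateAll is invariant to biomarker column order", {
    set.seed(24)
    X <- matrix(rnorm(50 * 4), 50, 4,
                dimnames = list(NULL, c("D", "B", "C", "A")))
    X[sample(200, 30)] <- NA
    e1 <- correlateAll(X, min_n = 10)
    e2 <- correlateAll(X[, c(3, 1, 4, 2)], min_n = 10)
    attr(e1, "untested") <- attr(e2, "untested") <- NULL
    expect_equal(e1, e2)
})

test_that("buildNetwork thresholds on q and keeps isolated nodes", {
    e <- data.frame(biomarker_a = c("A", "A", "B"),
                    biomarker_b = c("B", "C", "C"),
                    rho = c(-0.4, 0.1, 0.05), n = 100L,
                    p = c(0.001, 0.5, 0.9), q = c(0.01, 0.6, 0.9))
    net <- buildNetwork(e, alpha = 0.05)
    expect_equal(networkNodes(net), c("A", "B", "C"))
    expect_equal(nrow(networkEdges(net)), 1L)
    expect_equal(networkEdges(net)$rho, -0.4)
    ## all non-significant: nodes survive, no edges
    e$q <- 0.9
    net0 <- buildNetwork(e)
    expect_equal(length(networkNodes(net0)), 3L)
    expect_equal(nrow(networkEdges(net0)), 0L)
    g <- asIgraph(net0)
    expect_equal(igraph::vcount(g), 3)
    expect_equal(igraph::ecount(g), 0)
})

test_that("neighborhood returns the induced star of the focus", {
    e <- data.frame(biomarker_a = c("V", "V", "V", "L"),
                    biomarker_b = c("A", "B", "C", "A"),
                    rho = c(0.3, -0.2, 0.4, 0.5), n = 100L,
                    p = rep(0.001, 4), q = rep(0.01, 4))
    net <- buildNetwork(e, alpha = 0.05)
    star <- neighborhood(net, "V")
    expect_setequal(networkNodes(star), c("V", "A", "B", "C"))
    expect_equal(nrow(networkEdges(star)), 3L)
    expect_true(all(networkEdges(star)$biomarker_a == "V" |
                    networkEdges(star)$biomarker_b == "V"))
    ## isolated focus
    lone <- buildNetwork(e[e$q > 1, ], nodes = c("V", "Z"))
    expect_equal(networkNodes(neighborhood(lone, "Z")), "Z")
    expect_error(neighborhood(net, "QQQ"), "unknown biomarker")
})

test_that("sensitivityCompare aligns shared pairs and flags disjoint sets", {
    set.seed(25)
    X <- matrix(rnorm(200 * 6), 200, 6,
                dimnames = list(NULL, LETTERS[1:6]))
    e <- correlateAll(X, min_n = 10)
    self <- sensitivityCompare(e, e)
    expect_equal(self$r, 1)
    expect_equal(nrow(self$table), nrow(e))
    e2 <- e
    e2$biomarker_a <- paste0("X", e2$biomarker_a)
    e2$biomarker_b <- paste0("X", e2$biomarker_b)
    expect_error(sensitivityCompare(e, e2), "insufficient overlap")
})

test_that("a 70% subsample reproduces the full correlation profile", {
    cfg <- syntheticConfig(sprintf("B%02d", 1:12),
                           blocks = list(b1 = sprintf("B%02d", 1:4),
                                         b2 = sprintf("B%02d", 5:8)),
                           r_within = 0.6, n_participants = 600, seed = 31)
    ch <- generateCohort(cfg)
    pairs <- extractPairs(ch$table)
    full <- correlateAll(deltaMatrix(pairs))
    set.seed(32)
    keep <- sample(unique(pairs$participant_id),
                   round(0.7 * length(unique(pairs$participant_id))))
    sub <- correlateAll(deltaMatrix(pairs[pairs$participant_id %in% keep, ]))
    expect_gt(sensitivityCompare(full, sub)$r, 0.9)
})

test_that("network exports are written and loadable", {
    e <- data.frame(biomarker_a = "A", biomarker_b = "B", rho = 0.5,
                    n = 100L, p = 1e-5, q = 1e-4)
    net <- buildNetwork(e)
    tsv <- withr::local_tempfile(fileext = ".tsv")
    gml <- withr::local_tempfile(fileext = ".graphml")
    csv <- withr::local_tempfile(fileext = ".csv")
    writeEdgeList(net, tsv)
    writeGraphML(net, gml, clusters = c(A = 1L, B = 1L))
    writeCorrelationTable(e, csv)
    el <- read.delim(tsv)
    expect_equal(el$weight, 0.5)
    g <- igraph::read_graph(gml, format = "graphml")
    expect_equal(igraph::ecount(g), 1)
    expect_equal(read.csv(csv)$rho, 0.5)
})
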