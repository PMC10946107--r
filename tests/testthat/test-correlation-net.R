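test_that("spearman backend gives 1 for identical count rows and matches rank-then-Pearson", {
    m <- matrix(c(3, 6, 1, 3, 6, 1, 9, 2, 4), 3, 3, byrow = TRUE,
                dimnames = list(c("g1", "g2", "g3"), c("s1", "s2", "s3")))
    cm <- estimateCorrelations(CountTable(m, "X"), backend = "spearman")
    expect_equal(adjacency(cm)["g1", "g2"], 1.0)
    for (rep in 1:5) {
        set.seed(100 + rep)
        mm <- matrix(rpois(6 * 12, 50) + 1, 6, 12)
        ct <- toyCounts(mm)
        cm <- estimateCorrelations(ct, backend = "spearman")
        oracle <- rankThenPearson(abundances(toRelativeAbundance(ct)))
        expect_equal(unname(adjacency(cm)), unname(oracle),
                     tolerance = 1e-12)
    }
})

test_that("thresholding keeps only entries strictly above the threshold", {
    a <- diag(4)
    a[1, 2] <- a[2, 1] <- 0.5
    a[1, 3] <- a[3, 1] <- 0.41
    a[1, 4] <- a[4, 1] <- 0.39
    a[2, 3] <- a[3, 2] <- -0.2
    a[2, 4] <- a[4, 2] <- 0.4      # exactly at the default threshold
    a[3, 4] <- a[4, 3] <- -0.9
    dimnames(a) <- list(letters[1:4], letters[1:4])
    cm <- new("CorrelationMatrix", mat = a, backend = "precomputed")
    net <- thresholdToNetwork(cm, 0.4)
    expect_equal(edgeCount(net), 2L)                    # 0.5 and 0.41 only
    expect_equal(adjacency(net)["b", "d"], 0)           # boundary dropped
    expect_equal(adjacency(net)["c", "d"], 0)           # negative dropped
    expect_true(all(diag(adjacency(net)) == 0))
    expect_error(thresholdToNetwork(cm, 1), "\\[-1, 1\\)")
    expect_error(thresholdToNetwork(cm, -1.5), "\\[-1, 1\\)")
})

test_that("raising the threshold never adds edges or weight", {
    set.seed(42)
    a <- randomAdjacency(12, density = 0.6, lo = -1, hi = 1)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    cm <- new("CorrelationMatrix", mat = a, backend = "precomputed")
    sweep_ <- lapply(c(0.3, 0.4, 0.5), function(th)
        thresholdToNetwork(cm, th))
    ec <- vapply(sweep_, edgeCount, 1L)
    tw <- vapply(sweep_, totalEdgeWeight, 1.0)
    expect_true(all(diff(ec) <= 0))
    expect_true(all(diff(tw) <= 0))
})

test_that("pruning removes exactly the taxa isolated in both networks", {
    nm <- sprintf("g%d", 1:5)
    ax <- ay <- matrix(0, 5, 5, dimnames = list(nm, nm))
    ax[1, 2] <- ax[2, 1] <- 0.6          # g1-g2 edge in X only
    ay[3, 1] <- ay[1, 3] <- 0.5          # g3-g1 edge in Y only
    netX <- WeightedNetwork(ax, 0.4)
    netY <- WeightedNetwork(ay, 0.4)
    pr <- pruneJointlyIsolated(netX, netY)
    # g2 isolated in Y but not X -> retained; g4,g5 jointly isolated -> gone
    expect_identical(pr$effectiveTaxa, c("g1", "g2", "g3"))
    expect_identical(dim(adjacency(pr$netX)), c(3L, 3L))
    expect_equal(adjacency(pr$netX)["g1", "g2"], 0.6)
    expect_equal(adjacency(pr$netY)["g1", "g3"], 0.5)
    # idempotence
    pr2 <- pruneJointlyIsolated(pr$netX, pr$netY)
    expect_identical(pr2$effectiveTaxa, pr$effectiveTaxa)
    expect_equal(adjacency(pr2$netX), adjacency(pr$netX))
    # mismatched node lists are an error
    bad <- WeightedNetwork(ax[1:4, 1:4], 0.4)
    expect_error(pruneJointlyIsolated(netX, bad), "same ordered taxon list")
})

test_that("precomputed backend reorders a user matrix to the count table's taxa", {
    m <- matrix(c(10, 20, 5, 8, 30, 2), 3, 2,
                dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
    pm <- diag(3)
    dimnames(pm) <- list(c("g3", "g1", "g2"), c("g3", "g1", "g2"))
    pm["g1", "g3"] <- pm["g3", "g1"] <- 0.7
    cm <- estimateCorrelations(CountTable(m, "X"), backend = "precomputed",
                               precomputed = pm)
    expect_identical(taxa(cm), c("g1", "g2", "g3"))
    expect_equal(adjacency(cm)["g1", "g3"], 0.7)
    expect_error(estimateCorrelations(CountTable(m, "X"),
        backend = "precomputed", precomputed = pm[1:2, 1:2]), "lacks taxa")
})

test_that("edge lists and GraphML export round the network through disk", {
    set.seed(8)
    net <- WeightedNetwork(randomAdjacency(6, density = 0.5), 0.4)
    tsv <- withr::local_tempfile(fileext = ".tsv")
    el <- edgeList(net, tsv)
    expect_equal(nrow(el), edgeCount(net))
    back <- utils::read.delim(tsv)
    expect_equal(sum(back$weight), totalEdgeWeight(net), tolerance = 1e-9)
    gml <- withr::local_tempfile(fileext = ".graphml")
    writeGraphML(net, gml)
    g <- igraph::read_graph(gml, format = "graphml")
    expect_equal(igraph::gsize(g), edgeCount(net))
})
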