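test_that("the worked rewiring example gives intersection 0.4, union 1.8, score 1.4", {
    nm <- c("v", "b", "c", "d")
    ax <- ay <- matrix(0, 4, 4, dimnames = list(nm, nm))
    ax["v", "b"] <- ax["b", "v"] <- 0.5
    ax["v", "c"] <- ax["c", "v"] <- 0.7
    ay["v", "c"] <- ay["c", "v"] <- 0.4
    ay["v", "d"] <- ay["d", "v"] <- 0.6
    pair <- new("SubnetworkPair", nodes = nm, adjX = ax, adjY = ay)
    sc <- qnetdiffScores(pair)
    row <- sc[sc$taxon == "v", ]
    expect_equal(row$intersection, 0.4)
    expect_equal(row$union, 1.8)
    expect_equal(row$qnetdiff, 1.4)
    # brute-force L1 oracle agrees: |0.5-0| + |0.7-0.4| + |0-0.6|
    expect_equal(row$qnetdiff, sum(abs(ax["v", ] - ay["v", ])))
})

test_that("identical networks score zero everywhere; 0/1 networks count neighbour set differences", {
    set.seed(31)
    ax <- randomAdjacency(10, density = 0.4)
    pair <- new("SubnetworkPair", nodes = rownames(ax), adjX = ax, adjY = ax)
    expect_true(all(qnetdiffScores(pair)$qnetdiff == 0))
    for (rep in 1:5) {
        set.seed(400 + rep)
        pair <- randomSubnetworkPair(12, binary = TRUE)
        sc <- qnetdiffScores(pair)
        setDiffSize <- vapply(seq_len(12), function(i) {
            nx <- which(pair@adjX[i, ] > 0)
            ny <- which(pair@adjY[i, ] > 0)
            length(union(nx, ny)) - length(intersect(nx, ny))
        }, 1L)
        expect_identical(sc$qnetdiff, as.numeric(setDiffSize))
    }
})

test_that("scores equal the per-node L1 distance, symmetrically and non-negatively", {
    for (rep in 1:20) {
        set.seed(500 + rep)
        pair <- randomSubnetworkPair(sample(5:20, 1))
        sc <- qnetdiffScores(pair)
        expect_equal(sc$qnetdiff, unname(l1RowDistance(pair@adjX, pair@adjY)),
                     tolerance = 1e-12)
        swapped <- new("SubnetworkPair", nodes = pair@nodes,
                       adjX = pair@adjY, adjY = pair@adjX)
        expect_equal(qnetdiffScores(swapped)$qnetdiff, sc$qnetdiff,
                     tolerance = 1e-12)
        expect_true(all(sc$qnetdiff >= 0))
        # zero exactly when the weighted rows agree
        agree <- rowSums(abs(pair@adjX - pair@adjY)) == 0
        expect_identical(sc$qnetdiff == 0, unname(agree))
    }
})

test_that("the rewiring index satisfies the per-node triangle inequality", {
    set.seed(61)
    nm <- sprintf("n%02d", 1:8)
    mk <- function() {
        a <- randomAdjacency(8, density = 0.4)
        dimnames(a) <- list(nm, nm)
        a
    }
    ax <- mk(); ay <- mk(); az <- mk()
    qd <- function(a, b) qnetdiffScores(new("SubnetworkPair", nodes = nm,
                                            adjX = a, adjY = b))$qnetdiff
    expect_true(all(qd(ax, az) <= qd(ax, ay) + qd(ay, az) + 1e-12))
})

test_that("the subnetwork pair contains cores and their neighbours in either network", {
    nm <- c("a", "b", "c", "x")
    ax <- ay <- matrix(0, 4, 4, dimnames = list(nm, nm))
    ax["a", "b"] <- ax["b", "a"] <- 0.5       # a-b only in X
    ay["a", "c"] <- ay["c", "a"] <- 0.6       # a-c only in Y
    ax["b", "c"] <- ax["c", "b"] <- 0.45      # b-c edge inside V (X)
    ax["x", "x"] <- 0                          # x unrelated to the core
    netX <- WeightedNetwork(ax, 0.4)
    netY <- WeightedNetwork(ay, 0.4)
    pair <- buildCoreSubnetworks(netX, netY, "a")
    expect_identical(taxa(pair), c("a", "b", "c"))
    expect_equal(pair@adjX["b", "c"], 0.45)   # surviving V-internal edge
    # a core node isolated in both networks still enters V
    pair2 <- buildCoreSubnetworks(netX, netY, c("a", "x"))
    expect_true("x" %in% taxa(pair2))
    # empty core set -> empty networks
    empty <- buildCoreSubnetworks(netX, netY, character())
    expect_length(taxa(empty), 0L)
    expect_identical(nrow(qnetdiffScores(empty)), 0L)
    expect_error(buildCoreSubnetworks(netX, netY, "zz"), "absent")
})

test_that("the feature table reports degrees, abundances and p values sorted by score", {
    fix <- generateFixture(fixtureSpec(seed = 5))
    cfg <- qndConfig(fix$countsX, fix$countsY, fix$taxonomy, seed = 5)
    res <- runPipeline(cfg)
    tab <- res$scoreTable
    expect_identical(tab$taxon[1], fix$truth$rewiringTaxon)
    expect_true(all(diff(tab$qnetdiff) <= 0))
    # degrees recount the nonzero edges of the restricted networks
    i <- match(tab$taxon, taxa(res$pair))
    expect_identical(tab$degree_X, unname(rowSums(res$pair@adjX > 0))[i])
    expect_identical(tab$degree_Y, unname(rowSums(res$pair@adjY > 0))[i])
    expect_true(all(tab$p_value >= 0 & tab$p_value <= 1, na.rm = TRUE))
    expect_true(tab$is_core[tab$taxon == fix$truth$rewiringTaxon])
    # mean abundances come from the right group
    g1 <- tab$taxon[1]
    expect_equal(tab$mean_abund_X[1],
                 mean(abundances(res$abundX)[g1, ]))
    # the difference network's incident weight sums reproduce the scores
    dn <- differenceNetwork(res$pair)
    expect_equal(rowSums(adjacency(dn))[tab$taxon],
                 setNames(tab$qnetdiff, tab$taxon), tolerance = 1e-12)
})
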