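.twoCliques <- function(bridge = 0.41) {
    nm <- sprintf("g%d", 1:8)
    a <- matrix(0, 8, 8, dimnames = list(nm, nm))
    a[1:4, 1:4] <- 0.9
    a[5:8, 5:8] <- 0.9
    diag(a) <- 0
    a[4, 5] <- a[5, 4] <- bridge
    WeightedNetwork(a, 0.4)
}

test_that("Louvain splits two cliques joined by a weak edge, deterministically", {
    net <- .twoCliques()
    cl <- clusterNodes(net, seed = 9)
    expect_length(unique(cl[1:4]), 1L)
    expect_length(unique(cl[5:8]), 1L)
    expect_false(cl[["g1"]] == cl[["g8"]])
    expect_identical(cl, clusterNodes(net, seed = 9))
    # every node gets exactly one cluster id
    expect_identical(names(cl), taxa(net))
    expect_false(anyNA(cl))
})

test_that("similar groups are the equivalence classes of (family, cluster_X, cluster_Y)", {
    tax <- c(g1 = "famA", g2 = "famA", g3 = "famA", g4 = "famB")
    clX <- c(g1 = 1L, g2 = 1L, g3 = 1L, g4 = 1L)
    clY <- c(g1 = 2L, g2 = 2L, g3 = 2L, g4 = 2L)
    cm <- findSimilarGroups(tax, clX, clY)
    expect_identical(groupMembers(cm),
                     list(c("g1", "g2", "g3"), "g4"))
    # same family, different cluster in X -> split
    clX2 <- c(g1 = 1L, g2 = 5L, g3 = 1L, g4 = 1L)
    cm2 <- findSimilarGroups(tax, clX2, clY)
    expect_true(all(lengths(groupMembers(cm2)[
        vapply(groupMembers(cm2), function(m) "g2" %in% m, TRUE)]) == 1L))
    # same clusters in both, different family -> split
    tax2 <- c(g1 = "famA", g2 = "famC", g3 = "famA", g4 = "famB")
    cm3 <- findSimilarGroups(tax2, clX, clY)
    expect_identical(groupMembers(cm3),
                     list(c("g1", "g3"), "g2", "g4"))
    expect_error(findSimilarGroups(tax[1:3], clX, clY), "absent")
    expect_error(findSimilarGroups(tax, clX[1:3], clY), "same taxa")
})

test_that("representatives maximise the pooled mean abundance with lexicographic ties", {
    cm <- new("ContractionMap", members = list(c("a", "b"), "c"),
              representative = rep(NA_character_, 2),
              supCategory = c("f1", "f2"))
    atX <- toyAbundance(matrix(c(0.02, 0.05, 0.10), 3, 2,
        dimnames = list(c("a", "b", "c"), c("s1", "s2"))) * c(1, 1, 1))
    atY <- toyAbundance(matrix(c(0.02, 0.05, 0.10), 3, 2,
        dimnames = list(c("a", "b", "c"), c("t1", "t2"))))
    chosen <- chooseRepresentatives(cm, atX, atY)
    expect_identical(representatives(chosen), c("b", "c"))
    # argmax property: representative's pooled mean >= every member's
    pooled <- rowMeans(cbind(abundances(atX), abundances(atY)))
    for (g in seq_along(groupMembers(chosen)))
        expect_gte(pooled[representatives(chosen)[g]],
                   max(pooled[groupMembers(chosen)[[g]]]))
    # exact tie -> lexicographically first member
    atT <- toyAbundance(matrix(0.03, 3, 2,
        dimnames = list(c("a", "b", "c"), c("u1", "u2"))))
    tied <- chooseRepresentatives(cm, atT, atT)
    expect_identical(representatives(tied)[1], "a")
})

test_that("contraction averages existing inter-group edges (or all pairs on request)", {
    nm <- c("a", "b", "c")
    adj <- matrix(0, 3, 3, dimnames = list(nm, nm))
    adj["a", "c"] <- adj["c", "a"] <- 0.5      # b-c edge absent
    net <- WeightedNetwork(adj, 0.4)
    cm <- new("ContractionMap", members = list(c("a", "b"), "c"),
              representative = c("a", "c"), supCategory = c("f1", "f2"))
    con <- contractNetworks(net, cm)
    expect_equal(adjacency(con)["a", "c"], 0.5)    # mean over existing edges
    conAll <- contractNetworks(net, cm, mode = "all-pairs")
    expect_equal(adjacency(conAll)["a", "c"], 0.25) # (0.5 + 0) / 2
    # no inter-group edge -> weight 0
    adj0 <- matrix(0, 3, 3, dimnames = list(nm, nm))
    adj0["a", "b"] <- adj0["b", "a"] <- 0.9        # within-group only
    con0 <- contractNetworks(WeightedNetwork(adj0, 0.4), cm)
    expect_equal(adjacency(con0)["a", "c"], 0)
    expect_equal(adjacency(con0)["a", "a"], 0)     # within-group discarded
})

test_that("all-singleton contraction is the identity and member order is irrelevant", {
    set.seed(21)
    net <- WeightedNetwork(randomAdjacency(6, density = 0.5), 0.4)
    ids <- identityContraction(taxa(net))
    con <- contractNetworks(net, ids)
    expect_equal(adjacency(con), adjacency(net))
    # two multi-groups, member order permuted
    cm1 <- new("ContractionMap",
               members = list(taxa(net)[1:3], taxa(net)[4:6]),
               representative = c(taxa(net)[1], taxa(net)[4]),
               supCategory = c("f1", "f2"))
    cm2 <- new("ContractionMap",
               members = list(taxa(net)[c(3, 1, 2)], taxa(net)[c(6, 5, 4)]),
               representative = c(taxa(net)[1], taxa(net)[4]),
               supCategory = c("f1", "f2"))
    expect_equal(adjacency(contractNetworks(net, cm1)),
                 adjacency(contractNetworks(net, cm2)))
    expect_error(contractNetworks(net, new("ContractionMap",
        members = list(taxa(net)[1:3]), representative = taxa(net)[1],
        supCategory = "f1")), "partition")
})

test_that("nonzero contracted weights stay above the edge threshold", {
    for (rep in 1:10) {
        set.seed(300 + rep)
        a <- randomAdjacency(10, density = 0.4, lo = 0.4, hi = 1)
        net <- WeightedNetwork(a, 0.4)
        k <- sample(2:5, 1)
        grp <- sort(sample(seq_len(k), 10, replace = TRUE))
        mem <- split(taxa(net), grp)
        cm <- new("ContractionMap", members = unname(mem),
                  representative = vapply(mem, `[`, "", 1L),
                  supCategory = sprintf("f%d", seq_along(mem)))
        con <- contractNetworks(net, cm)
        w <- adjacency(con)[upper.tri(adjacency(con))]
        expect_true(all(w[w > 0] > 0.4))
        expect_equal(nrow(adjacency(con)), length(mem))
    }
})
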