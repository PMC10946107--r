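# Independent oracles and small generators used across the suite. These are
# deliberately brute-force and share no code with the implementation paths
# they check.

# Exhaustive-permutation one-sided Mann-Whitney p value for the alternative
# "y stochastically greater than x": U = #{(i,j): y_i > x_j}, p = fraction of
# relabelings with U at least as large as observed.
permutationPGreater <- function(x, y) {
    pooled <- c(x, y)
    m <- length(y)
    uStat <- function(yv, xv) sum(outer(yv, xv, ">")) +
        0.5 * sum(outer(yv, xv, "=="))
    obs <- uStat(y, x)
    labelings <- utils::combn(length(pooled), m)
    u <- apply(labelings, 2L, function(idx)
        uStat(pooled[idx], pooled[-idx]))
    mean(u >= obs - 1e-12)
}

# Spearman as literally "rank each row, then Pearson".
rankThenPearson <- function(mat) {
    r <- t(apply(mat, 1L, rank))
    stats::cor(t(r))
}

# Per-node L1 distance between two adjacency matrices: the scoring identity
# QNetDiff[v] == sum_w |A_X[v,w] - A_Y[v,w]|.
l1RowDistance <- function(ax, ay) rowSums(abs(ax - ay))

# Random symmetric weight matrix: weights in (lo, hi], zero diagonal.
randomAdjacency <- function(n, density = 0.3, lo = 0.4, hi = 1) {
    a <- matrix(0, n, n)
    up <- which(upper.tri(a))
    on <- up[stats::runif(length(up)) < density]
    a[on] <- lo + stats::runif(length(on)) * (hi - lo)
    a <- a + t(a)
    dimnames(a) <- list(sprintf("n%02d", seq_len(n)),
                        sprintf("n%02d", seq_len(n)))
    a
}

randomSubnetworkPair <- function(n, density = 0.3, binary = FALSE) {
    ax <- randomAdjacency(n, density)
    ay <- randomAdjacency(n, density)
    if (binary) { ax[ax > 0] <- 1; ay[ay > 0] <- 1 }
    new("SubnetworkPair", nodes = rownames(ax), adjX = ax, adjY = ay)
}

# Tiny count table with named rows for io tests.
toyCounts <- function(m, group = "X") {
    if (is.null(rownames(m)))
        rownames(m) <- sprintf("g%d", seq_len(nrow(m)))
    if (is.null(colnames(m)))
        colnames(m) <- sprintf("s%d", seq_len(ncol(m)))
    CountTable(m, group)
}

# Abundance table straight from a matrix (bypasses normalisation on purpose).
toyAbundance <- function(m, group = "X") {
    if (is.null(rownames(m)))
        rownames(m) <- sprintf("g%d", seq_len(nrow(m)))
    if (is.null(colnames(m)))
        colnames(m) <- sprintf("s%d", seq_len(ncol(m)))
    new("AbundanceTable", abund = m, group = group)
}
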