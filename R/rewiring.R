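# Steps 4-5: restrict both contracted networks to the core bacteria and
# their neighbours, then score each node by the edge-weighted symmetric
# difference of its incident edges between the two networks.

#' Build the core + related-bacteria subnetwork pair
#'
#' `V` is the union of the core taxa and every node adjacent to a core taxon
#' in at least one of the two contracted networks; `A_X` (`A_Y`) is group X's
#' (Y's) adjacency restricted to edges with both ends in `V`. An empty core
#' set yields an empty pair.
#'
#' @param netX,netY contracted [WeightedNetwork]s over the same node list.
#' @param core a [CoreSet] (or character vector of core taxa).
#' @return a [SubnetworkPair].
#' @export
buildCoreSubnetworks <- function(netX, netY, core) {
    stopifnot(is(netX, "WeightedNetwork"), is(netY, "WeightedNetwork"))
    if (!identical(taxa(netX), taxa(netY)))
        stop("networks must share the same ordered node list")
    coreNodes <- if (is(core, "CoreSet")) coreTaxa(core) else as.character(core)
    bad <- setdiff(coreNodes, taxa(netX))
    if (length(bad))
        stop("core taxa absent from the networks: ",
             paste(bad, collapse = ", "))
    nodes <- taxa(netX)
    inCore <- nodes %in% coreNodes
    nbr <- if (any(inCore))
        (rowSums(netX@adj[, inCore, drop = FALSE] > 0) +
         rowSums(netY@adj[, inCore, drop = FALSE] > 0)) > 0
    else rep(FALSE, length(nodes))
    keep <- inCore | nbr
    v <- nodes[keep]
    new("SubnetworkPair", nodes = v,
        adjX = netX@adj[keep, keep, drop = FALSE],
        adjY = netY@adj[keep, keep, drop = FALSE])
}

#' Node-level rewiring index (QNetDiff score)
#'
#' For each node `v`, over the union neighbourhood `N(v)` (absent edges
#' contribute weight 0):
#' \deqn{A_{X\cap Y}[v] = \sum_{w} \min(A_X[v,w], A_Y[v,w])}
#' \deqn{A_{X\cup Y}[v] = \sum_{w} \max(A_X[v,w], A_Y[v,w])}
#' and the rewiring index is their difference, the size of the edge-weighted
#' symmetric difference:
#' \deqn{QNetDiff[v] = A_{X\cup Y}[v] - A_{X\cap Y}[v].}
#' On 0/1-weighted networks this reduces to the cardinality of the symmetric
#' difference of `v`'s neighbour sets. Scores are non-negative, symmetric in
#' the two networks, and zero exactly when `v`'s weighted rows agree.
#'
#' @param pair a [SubnetworkPair].
#' @return data.frame with columns `taxon`, `intersection`, `union`,
#'   `qnetdiff`, in node order.
#' @export
qnetdiffScores <- function(pair) {
    stopifnot(is(pair, "SubnetworkPair"))
    ax <- pair@adjX
    ay <- pair@adjY
    if (nrow(ax) && (max(abs(ax - t(ax))) > 1e-9 ||
                     max(abs(ay - t(ay))) > 1e-9))
        stop("adjacency matrices must be symmetric")
    inter <- rowSums(pmin(ax, ay))
    uni <- rowSums(pmax(ax, ay))
    data.frame(taxon = pair@nodes, intersection = unname(inter),
               union = unname(uni), qnetdiff = unname(uni - inter),
               stringsAsFactors = FALSE)
}

#' Per-node feature table (main output)
#'
#' Combines the rewiring index with per-network degree, per-group mean
#' relative abundance, the core-selection p value and the core flag; sorted
#' by score (descending, ties by taxon name). Nodes without a p value (never
#' tested as representatives) get `NA`.
#'
#' @param pair a [SubnetworkPair].
#' @param atX,atY [AbundanceTable]s for the two groups.
#' @param core a [CoreSet] carrying the representatives' p values.
#' @param path optional TSV output path.
#' @return data.frame with columns `taxon`, `qnetdiff`, `degree_X`,
#'   `degree_Y`, `mean_abund_X`, `mean_abund_Y`, `p_value`, `is_core`.
#' @export
featureTable <- function(pair, atX, atY, core, path = NULL) {
    stopifnot(is(pair, "SubnetworkPair"), is(atX, "AbundanceTable"),
              is(atY, "AbundanceTable"), is(core, "CoreSet"))
    sc <- qnetdiffScores(pair)
    v <- pair@nodes
    p <- pValues(core)
    meanAb <- function(at, tx)
        ifelse(tx %in% taxa(at), rowMeans(at@abund)[tx], NA_real_)
    df <- data.frame(
        taxon = v,
        qnetdiff = sc$qnetdiff,
        degree_X = unname(rowSums(pair@adjX > 0)),
        degree_Y = unname(rowSums(pair@adjY > 0)),
        mean_abund_X = unname(meanAb(atX, v)),
        mean_abund_Y = unname(meanAb(atY, v)),
        p_value = unname(p[v]),
        is_core = v %in% coreTaxa(core),
        stringsAsFactors = FALSE)
    df <- df[order(-df$qnetdiff, df$taxon), , drop = FALSE]
    rownames(df) <- NULL
    if (!is.null(path))
        utils::write.table(df, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    df
}

#' Per-edge absolute difference network
#'
#' Network over the subnetwork pair's nodes whose edge weights are
#' `|A_X - A_Y|`; the weight sum of edges incident to a node equals its
#' QNetDiff score. Useful for visualising where the rewiring happens.
#'
#' @param pair a [SubnetworkPair].
#' @return a [WeightedNetwork].
#' @export
differenceNetwork <- function(pair) {
    stopifnot(is(pair, "SubnetworkPair"))
    WeightedNetwork(abs(pair@adjX - pair@adjY))
}

#' Plot the rewiring difference network
#'
#' Static plot of [differenceNetwork()] with node area proportional to the
#' QNetDiff score and edge width to the per-edge weight difference.
#'
#' @param pair a [SubnetworkPair].
#' @param ... passed on to [igraph::plot.igraph()].
#' @return invisibly, the difference network's igraph object.
#' @export
plotRewiring <- function(pair, ...) {
    stopifnot(is(pair, "SubnetworkPair"))
    dn <- differenceNetwork(pair)
    sc <- qnetdiffScores(pair)
    g <- .asIgraph(dn)
    size <- 8 + 20 * sqrt(sc$qnetdiff / max(sc$qnetdiff, 1e-12))
    ew <- igraph::E(g)$weight
    plot(g, vertex.size = size,
         edge.width = 1 + 4 * ew / max(ew, 1e-12), ...)
    invisible(g)
}
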