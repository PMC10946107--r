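# Step 2: false correlations between closely related taxa (multi-mapped reads
# split among siblings) are removed by contracting groups of similar taxa to
# a single representative node.

#' Cluster network nodes with the Louvain method
#'
#' Weighted-modularity community detection via [igraph::cluster_louvain()],
#' run under a fixed seed so the partition is reproducible. Taxa without any
#' edge form singleton communities.
#'
#' @param net a nonempty [WeightedNetwork].
#' @param seed integer seed fixing the Louvain randomisation.
#' @return named integer vector mapping each taxon to a cluster id.
#' @export
clusterNodes <- function(net, seed = 42) {
    stopifnot(is(net, "WeightedNetwork"))
    if (nrow(net@adj) == 0L)
        stop("cannot cluster an empty network")
    g <- .asIgraph(net)
    cl <- withSeed(seed, igraph::cluster_louvain(g))
    stats::setNames(as.integer(igraph::membership(cl)), taxa(net))
}

#' Determine similar-bacteria groups to be contracted
#'
#' Two effective taxa belong to the same similar-bacteria group iff
#' (1) they share the parent-level taxonomic category (`sup_category`) and
#' (2) they fall in the same Louvain cluster in group X's network AND in
#' group Y's network. The groups are therefore the equivalence classes of the
#' key `(sup_category, cluster_X, cluster_Y)`; maximality is automatic.
#' Representatives are not yet assigned (see [chooseRepresentatives()]).
#'
#' @param taxonomy named character vector, taxon -> parent-level name.
#' @param clX,clY named integer cluster assignments from [clusterNodes()],
#'   covering the same taxa.
#' @return a [ContractionMap] partitioning the effective taxa.
#' @export
findSimilarGroups <- function(taxonomy, clX, clY) {
    if (!identical(sort(names(clX)), sort(names(clY))))
        stop("cluster assignments must cover the same taxa")
    tx <- names(clX)
    checkTaxonomyCovers(taxonomy, tx)
    key <- paste(taxonomy[tx], clX[tx], clY[tx], sep = "\r")
    members <- split(tx, key)
    # stable order: by first member's position in the effective taxon list
    members <- members[order(vapply(members, function(m) min(match(m, tx)),
                                    1L))]
    members <- lapply(members, function(m) m[order(match(m, tx))])
    names(members) <- NULL
    new("ContractionMap", members = members,
        representative = rep(NA_character_, length(members)),
        supCategory = vapply(members, function(m) unname(taxonomy[m[1L]]),
                             ""))
}

#' Choose each group's representative taxon
#'
#' The representative of a similar-bacteria group is its member with the
#' highest mean relative abundance over the pooled samples of both groups;
#' ties are broken lexicographically by taxon name for reproducibility.
#'
#' @param cmap a [ContractionMap] (representatives may be unset).
#' @param atX,atY [AbundanceTable]s covering all member taxa.
#' @return the [ContractionMap] with representatives filled in.
#' @export
chooseRepresentatives <- function(cmap, atX, atY) {
    stopifnot(is(cmap, "ContractionMap"), is(atX, "AbundanceTable"),
              is(atY, "AbundanceTable"))
    mem <- unlist(cmap@members, use.names = FALSE)
    missing <- setdiff(mem, intersect(taxa(atX), taxa(atY)))
    if (length(missing))
        stop("abundance tables lack taxa: ", paste(missing, collapse = ", "))
    pooledMean <- (rowSums(atX@abund[mem, , drop = FALSE]) +
                   rowSums(atY@abund[mem, , drop = FALSE])) /
        (ncol(atX@abund) + ncol(atY@abund))
    reps <- vapply(cmap@members, function(m) {
        mu <- pooledMean[m]
        cand <- m[mu == max(mu)]
        sort(cand)[1L]
    }, "")
    new("ContractionMap", members = cmap@members, representative = reps,
        supCategory = cmap@supCategory)
}

#' The identity contraction (skip option)
#'
#' Every taxon becomes a singleton group representing itself. Running the
#' pipeline with this map is equivalent to skipping the contraction step.
#'
#' @param taxaNames character vector of effective taxa.
#' @param taxonomy optional named character vector for the `sup_category`
#'   column of the output (empty strings when absent).
#' @return a [ContractionMap] of singletons.
#' @export
identityContraction <- function(taxaNames, taxonomy = NULL) {
    sup <- if (is.null(taxonomy)) rep("", length(taxaNames))
           else unname(taxonomy[taxaNames])
    new("ContractionMap", members = as.list(taxaNames),
        representative = taxaNames, supCategory = sup)
}

#' Contract a network over a similar-bacteria partition
#'
#' Each group becomes one node labelled by its representative. The weight
#' between two groups is, in the default `"edges"` mode, the arithmetic mean
#' of the existing (nonzero) edge weights between their members, or 0 when no
#' such edge exists — so every nonzero contracted weight remains above the
#' original edge threshold. Mode `"all-pairs"` averages over all member pairs
#' instead (absent edges entering as 0). Within-group edges are discarded.
#'
#' @param net a [WeightedNetwork] whose node list `cmap` partitions.
#' @param cmap a [ContractionMap] with representatives chosen.
#' @param mode `"edges"` (mean over existing edges; default) or
#'   `"all-pairs"`.
#' @return a [WeightedNetwork] with one node per group.
#' @export
contractNetworks <- function(net, cmap, mode = c("edges", "all-pairs")) {
    stopifnot(is(net, "WeightedNetwork"), is(cmap, "ContractionMap"))
    mode <- match.arg(mode)
    if (anyNA(cmap@representative))
        stop("representatives must be chosen before contraction")
    mem <- unlist(cmap@members, use.names = FALSE)
    if (!setequal(mem, taxa(net)) || length(mem) != length(taxa(net)))
        stop("contraction map must partition the network's node list")
    k <- length(cmap@members)
    grp <- integer(nrow(net@adj))
    names(grp) <- taxa(net)
    for (g in seq_len(k)) grp[cmap@members[[g]]] <- g
    # indicator matrix taxa x groups
    Z <- matrix(0, nrow(net@adj), k)
    Z[cbind(seq_along(grp), grp)] <- 1
    wsum <- t(Z) %*% net@adj %*% Z
    npair <- if (mode == "edges") t(Z) %*% (net@adj > 0) %*% Z
             else outer(lengths(cmap@members), lengths(cmap@members))
    a <- ifelse(npair > 0, wsum / pmax(npair, 1), 0)
    a[npair == 0] <- 0
    diag(a) <- 0
    dimnames(a) <- list(cmap@representative, cmap@representative)
    WeightedNetwork(a, threshold = net@threshold)
}

#' Tabulate a ContractionMap
#'
#' One row per unified group: `group_id`, `sup_category`, `representative`
#' and the semicolon-joined member list.
#'
#' @param cmap a [ContractionMap].
#' @param path optional TSV output path.
#' @return data.frame, invisibly written to `path` when given.
#' @export
contractionTable <- function(cmap, path = NULL) {
    stopifnot(is(cmap, "ContractionMap"))
    df <- data.frame(
        group_id = seq_along(cmap@members),
        sup_category = cmap@supCategory,
        representative = cmap@representative,
        members = vapply(cmap@members, paste, "", collapse = ";"),
        stringsAsFactors = FALSE)
    if (!is.null(path))
        utils::write.table(df, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    df
}
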