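#' Estimate between-taxon correlations for one group
#'
#' Front end for the three correlation backends. `"sparcc"` (default) runs the
#' compositionally aware basis-correlation inference of [sparccCorrelation()]
#' on the raw counts; `"spearman"` is a deterministic rank-correlation
#' fallback computed on relative abundances (rank correlation is
#' depth-invariant only after closure); `"precomputed"` wraps a user-supplied
#' square matrix (e.g. from [readCorrelationMatrix()]).
#'
#' @param ct a [CountTable].
#' @param backend one of `"sparcc"`, `"spearman"`, `"precomputed"`.
#' @param seed integer seed for the sparcc resampling.
#' @param iterations,exclusionThreshold,exclusionRounds,pseudoCount sparcc
#'   parameters, see [sparccCorrelation()].
#' @param precomputed square numeric matrix with taxon dimnames (only for
#'   `backend = "precomputed"`); it is reordered to the count table's taxa.
#' @return a [CorrelationMatrix] over the count table's taxa.
#' @export
estimateCorrelations <- function(ct,
                                 backend = c("sparcc", "spearman",
                                             "precomputed"),
                                 seed = 1, iterations = 20,
                                 exclusionThreshold = 0.1,
                                 exclusionRounds = 10, pseudoCount = 1,
                                 precomputed = NULL) {
    stopifnot(is(ct, "CountTable"))
    backend <- match.arg(backend)
    m <- switch(backend,
        sparcc = sparccCorrelation(ct@counts, iterations = iterations,
                                   exclusionThreshold = exclusionThreshold,
                                   exclusionRounds = exclusionRounds,
                                   pseudoCount = pseudoCount, seed = seed),
        spearman = {
            ab <- abundances(toRelativeAbundance(ct))
            r <- stats::cor(t(ab), method = "spearman")
            diag(r) <- 1
            r
        },
        precomputed = {
            if (is.null(precomputed))
                stop("backend 'precomputed' needs a correlation matrix")
            pm <- as.matrix(precomputed)
            missing <- setdiff(taxa(ct), rownames(pm))
            if (length(missing))
                stop("precomputed matrix lacks taxa: ",
                     paste(missing, collapse = ", "))
            pm[taxa(ct), taxa(ct), drop = FALSE]
        })
    # constant rows (zero variance) leave NA under spearman; no information,
    # no correlation
    m[is.na(m)] <- 0
    diag(m) <- 1
    m <- (m + t(m)) / 2
    new("CorrelationMatrix", mat = m, backend = backend)
}

#' Read a precomputed correlation matrix
#'
#' Square tab-delimited matrix with matching row and column taxon labels
#' (first column holds the row labels).
#'
#' @param path path to the TSV file.
#' @return numeric matrix suitable for
#'   `estimateCorrelations(backend = "precomputed")`.
#' @export
readCorrelationMatrix <- function(path) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE, row.names = 1L)
    m <- as.matrix(df)
    if (!identical(rownames(m), colnames(m)))
        stop("correlation matrix '", path,
             "' must have matching row/column labels")
    m
}

#' Threshold a correlation matrix into a weighted network
#'
#' An entry becomes an edge weight iff it is strictly greater than
#' `edgeThreshold`; entries equal to or below the threshold (including all
#' negative correlations) become 0, and the diagonal is forced to 0. The
#' default 0.4 is the conventional cutoff for microbial co-occurrence
#' networks.
#'
#' @param cm a [CorrelationMatrix].
#' @param edgeThreshold edge threshold in `[-1, 1)`.
#' @return a [WeightedNetwork] over the same taxa.
#' @export
thresholdToNetwork <- function(cm, edgeThreshold = 0.4) {
    stopifnot(is(cm, "CorrelationMatrix"))
    if (!is.numeric(edgeThreshold) || length(edgeThreshold) != 1L ||
        is.na(edgeThreshold) || edgeThreshold < -1 || edgeThreshold >= 1)
        stop("edgeThreshold must be a single value in [-1, 1)")
    a <- cm@mat
    a[a <= edgeThreshold] <- 0
    diag(a) <- 0
    WeightedNetwork(a, threshold = edgeThreshold)
}

#' Remove taxa isolated in both networks
#'
#' A taxon is dropped only when it has degree 0 in group X's network AND in
#' group Y's network; a taxon with an edge in either network is retained in
#' both ("effective bacteria"). The surviving adjacency submatrices are
#' unchanged and both outputs share the same node list.
#'
#' @param netX,netY [WeightedNetwork]s over the same ordered taxon list.
#' @return list with elements `netX`, `netY` (pruned networks) and
#'   `effectiveTaxa` (ordered character vector).
#' @export
pruneJointlyIsolated <- function(netX, netY) {
    stopifnot(is(netX, "WeightedNetwork"), is(netY, "WeightedNetwork"))
    if (!identical(taxa(netX), taxa(netY)))
        stop("networks must share the same ordered taxon list")
    keep <- networkDegrees(netX) > 0 | networkDegrees(netY) > 0
    eff <- taxa(netX)[keep]
    list(
        netX = WeightedNetwork(netX@adj[keep, keep, drop = FALSE],
                               netX@threshold),
        netY = WeightedNetwork(netY@adj[keep, keep, drop = FALSE],
                               netY@threshold),
        effectiveTaxa = eff)
}

#' Export a network as a weighted edge list or GraphML
#'
#' `edgeList()` returns (and optionally writes) the undirected edges as a
#' three-column table `u, v, weight`; `writeGraphML()` writes the network in
#' GraphML via igraph.
#'
#' @param net a [WeightedNetwork].
#' @param path optional output TSV path / GraphML path.
#' @return `edgeList`: data.frame of edges; `writeGraphML`: `path`, invisibly.
#' @export
edgeList <- function(net, path = NULL) {
    stopifnot(is(net, "WeightedNetwork"))
    idx <- which(upper.tri(net@adj) & net@adj > 0, arr.ind = TRUE)
    nm <- as.character(taxa(net))
    df <- data.frame(u = nm[idx[, 1L]], v = nm[idx[, 2L]],
                     weight = net@adj[idx], stringsAsFactors = FALSE)
    df <- df[order(df$u, df$v), , drop = FALSE]
    rownames(df) <- NULL
    if (!is.null(path))
        utils::write.table(df, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    df
}

#' @rdname edgeList
#' @export
writeGraphML <- function(net, path) {
    stopifnot(is(net, "WeightedNetwork"))
    g <- .asIgraph(net)
    igraph::write_graph(g, path, format = "graphml")
    invisible(path)
}

.asIgraph <- function(net) {
    igraph::graph_from_adjacency_matrix(net@adj, mode = "undirected",
                                        weighted = TRUE, diag = FALSE)
}
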