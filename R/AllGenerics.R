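#' Accessors for qnetdiff classes
#'
#' Small accessor layer so downstream code never touches slots directly:
#' `taxa()` returns the ordered taxon list of a table, matrix or network;
#' `sampleIDs()` the sample identifiers; `groupLabel()` the group tag;
#' `counts()`/`abundances()` the underlying matrices; `adjacency()` the weight
#' matrix of a network; `representatives()`, `groupMembers()` the contraction
#' partition; `coreTaxa()` and `pValues()` the core-selection result.
#'
#' @param object a qnetdiff S4 object.
#' @return the component named by the accessor.
#' @name accessors
#' @examples
#' ct <- CountTable(matrix(1:6, 3, 2,
#'     dimnames = list(c("g1", "g2", "g3"), c("s1", "s2"))), "X")
#' taxa(ct)
#' counts(ct)
NULL

#' @rdname accessors
#' @export
setGeneric("taxa", function(object) standardGeneric("taxa"))
#' @rdname accessors
#' @export
setGeneric("sampleIDs", function(object) standardGeneric("sampleIDs"))
#' @rdname accessors
#' @export
setGeneric("groupLabel", function(object) standardGeneric("groupLabel"))
#' @rdname accessors
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))
#' @rdname accessors
#' @export
setGeneric("abundances", function(object) standardGeneric("abundances"))
#' @rdname accessors
#' @export
setGeneric("adjacency", function(object) standardGeneric("adjacency"))
#' @rdname accessors
#' @export
setGeneric("representatives", function(object) standardGeneric("representatives"))
#' @rdname accessors
#' @export
setGeneric("groupMembers", function(object) standardGeneric("groupMembers"))
#' @rdname accessors
#' @export
setGeneric("coreTaxa", function(object) standardGeneric("coreTaxa"))
#' @rdname accessors
#' @export
setGeneric("pValues", function(object) standardGeneric("pValues"))

#' @rdname accessors
setMethod("taxa", "CountTable", function(object) rownames(object@counts))
#' @rdname accessors
setMethod("taxa", "AbundanceTable", function(object) rownames(object@abund))
#' @rdname accessors
setMethod("taxa", "CorrelationMatrix", function(object) rownames(object@mat))
#' @rdname accessors
setMethod("taxa", "WeightedNetwork", function(object) rownames(object@adj))
#' @rdname accessors
setMethod("taxa", "SubnetworkPair", function(object) object@nodes)

#' @rdname accessors
setMethod("sampleIDs", "CountTable", function(object) colnames(object@counts))
#' @rdname accessors
setMethod("sampleIDs", "AbundanceTable", function(object) colnames(object@abund))

#' @rdname accessors
setMethod("groupLabel", "CountTable", function(object) object@group)
#' @rdname accessors
setMethod("groupLabel", "AbundanceTable", function(object) object@group)

#' @rdname accessors
setMethod("counts", "CountTable", function(object) object@counts)
#' @rdname accessors
setMethod("abundances", "AbundanceTable", function(object) object@abund)

#' @rdname accessors
setMethod("adjacency", "WeightedNetwork", function(object) object@adj)
#' @rdname accessors
setMethod("adjacency", "CorrelationMatrix", function(object) object@mat)

#' @rdname accessors
setMethod("representatives", "ContractionMap",
    function(object) object@representative)
#' @rdname accessors
setMethod("groupMembers", "ContractionMap", function(object) object@members)

#' @rdname accessors
setMethod("coreTaxa", "CoreSet", function(object) object@core)
#' @rdname accessors
setMethod("pValues", "CoreSet", function(object) object@pValues)

#' Degrees and edge summaries of a WeightedNetwork
#'
#' `networkDegrees()` counts the nonzero-weight edges incident to each node;
#' `edgeCount()` the number of distinct edges; `totalEdgeWeight()` their
#' weight sum (each undirected edge counted once).
#'
#' @param net a [WeightedNetwork].
#' @return named integer vector / single number.
#' @export
networkDegrees <- function(net) {
    stopifnot(is(net, "WeightedNetwork"))
    rowSums(net@adj > 0)
}

#' @rdname networkDegrees
#' @export
edgeCount <- function(net) {
    stopifnot(is(net, "WeightedNetwork"))
    sum(net@adj[upper.tri(net@adj)] > 0)
}

#' @rdname networkDegrees
#' @export
totalEdgeWeight <- function(net) {
    stopifnot(is(net, "WeightedNetwork"))
    sum(net@adj[upper.tri(net@adj)])
}

setMethod("show", "CountTable", function(object) {
    cat(sprintf("CountTable (group %s): %d taxa x %d samples, total count %.0f\n",
        object@group, nrow(object@counts), ncol(object@counts),
        sum(object@counts)))
})

setMethod("show", "AbundanceTable", function(object) {
    cs <- colSums(object@abund)
    cat(sprintf(
        "AbundanceTable (group %s): %d taxa x %d samples, column sums %.4g-%.4g\n",
        object@group, nrow(object@abund), ncol(object@abund),
        if (length(cs)) min(cs) else NA, if (length(cs)) max(cs) else NA))
})

setMethod("show", "CorrelationMatrix", function(object) {
    cat(sprintf("CorrelationMatrix (%s): %d taxa\n", object@backend,
                nrow(object@mat)))
})

setMethod("show", "WeightedNetwork", function(object) {
    cat(sprintf(
        "WeightedNetwork: %d nodes, %d edges, total weight %.3f (threshold %s)\n",
        nrow(object@adj), edgeCount(object), totalEdgeWeight(object),
        format(object@threshold)))
})

setMethod("show", "ContractionMap", function(object) {
    k <- length(object@members)
    multi <- sum(lengths(object@members) > 1L)
    cat(sprintf(
        "ContractionMap: %d taxa in %d groups (%d multi-taxon)\n",
        length(unlist(object@members)), k, multi))
})

setMethod("show", "CoreSet", function(object) {
    cat(sprintf(
        "CoreSet (focus %s, p < %g): %d core of %d representatives\n",
        object@focus, object@pThreshold, length(object@core),
        length(object@pValues)))
})

setMethod("show", "SubnetworkPair", function(object) {
    cat(sprintf(
        "SubnetworkPair: %d nodes; %d edges in G_X, %d in G_Y\n",
        length(object@nodes),
        sum(object@adjX[upper.tri(object@adjX)] > 0),
        sum(object@adjY[upper.tri(object@adjY)] > 0)))
})
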