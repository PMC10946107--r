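#' @import methods
NULL

.checkTaxaNames <- function(nm, what, n = 1L) {
    if (n == 0L) return(NULL)    # empty objects are legal (e.g. empty core)
    if (is.null(nm) || any(is.na(nm)) || any(!nzchar(nm)))
        return(sprintf("%s must have non-empty taxon names", what))
    dup <- nm[duplicated(nm)]
    if (length(dup))
        return(sprintf("duplicate taxon names in %s: %s", what,
                       paste(unique(dup), collapse = ", ")))
    NULL
}

#' CountTable: taxa-by-sample counts for one sample group
#'
#' Non-negative integer counts with taxa as rows (unique names) and samples as
#' columns, tagged with the group label (conventionally `"X"` or `"Y"`).
#' At least two samples are required so that between-sample statistics are
#' defined.
#'
#' @slot counts numeric matrix of non-negative integer-valued counts, with
#'   rownames (taxa) and colnames (sample IDs).
#' @slot group single character label for the sample group.
#' @aliases CountTable
#' @exportClass CountTable
setClass("CountTable",
    slots = c(counts = "matrix", group = "character"))

setValidity("CountTable", function(object) {
    m <- object@counts
    msgs <- character()
    if (length(object@group) != 1L || is.na(object@group) ||
        !nzchar(object@group))
        msgs <- c(msgs, "group must be a single non-empty label")
    tn <- .checkTaxaNames(rownames(m), "counts", nrow(m))
    if (!is.null(tn)) msgs <- c(msgs, tn)
    if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
        msgs <- c(msgs, "counts must have unique sample IDs as colnames")
    if (ncol(m) < 2L)
        msgs <- c(msgs, "a group needs at least 2 samples")
    if (!is.numeric(m) || anyNA(m))
        msgs <- c(msgs, "counts must be numeric without NA")
    else {
        if (any(m < 0))
            msgs <- c(msgs, "counts must be non-negative")
        if (any(abs(m - round(m)) > 1e-8))
            msgs <- c(msgs, "counts must be integer-valued")
    }
    if (length(msgs)) msgs else TRUE
})

#' @describeIn CountTable-class constructor
#' @param counts taxa-by-sample matrix of non-negative integers.
#' @param group group label, e.g. `"X"`.
#' @export
CountTable <- function(counts, group) {
    new("CountTable", counts = as.matrix(counts), group = as.character(group))
}

#' AbundanceTable: per-sample relative abundances
#'
#' Same shape as a [CountTable] but holding relative abundances in `[0, 1]`.
#' Directly after normalisation every sample column sums to 1; after removal
#' of an "unclassified" row columns may sum to less than 1.
#'
#' @slot abund numeric matrix of relative abundances (taxa x samples).
#' @slot group single character group label.
#' @aliases AbundanceTable
#' @exportClass AbundanceTable
setClass("AbundanceTable",
    slots = c(abund = "matrix", group = "character"))

setValidity("AbundanceTable", function(object) {
    m <- object@abund
    msgs <- character()
    tn <- .checkTaxaNames(rownames(m), "abundances", nrow(m))
    if (!is.null(tn)) msgs <- c(msgs, tn)
    if (!is.numeric(m) || anyNA(m))
        msgs <- c(msgs, "abundances must be numeric without NA")
    else {
        if (any(m < -1e-12) || any(m > 1 + 1e-9))
            msgs <- c(msgs, "abundances must lie in [0, 1]")
        cs <- colSums(m)
        if (nrow(m) && any(cs > 1 + 1e-9))
            msgs <- c(msgs, "sample columns must sum to at most 1")
    }
    if (length(msgs)) msgs else TRUE
})

#' CorrelationMatrix: pairwise between-taxon correlation estimates
#'
#' Symmetric matrix of correlation coefficients in `[-1, 1]` over an ordered
#' taxon list, diagonal fixed at 1.
#'
#' @slot mat symmetric numeric matrix with identical row/column taxon names.
#' @slot backend character; how the estimates were obtained
#'   (`"sparcc"`, `"spearman"` or `"precomputed"`).
#' @aliases CorrelationMatrix
#' @exportClass CorrelationMatrix
setClass("CorrelationMatrix",
    slots = c(mat = "matrix", backend = "character"))

setValidity("CorrelationMatrix", function(object) {
    m <- object@mat
    msgs <- character()
    tn <- .checkTaxaNames(rownames(m), "correlation matrix", nrow(m))
    if (!is.null(tn)) msgs <- c(msgs, tn)
    if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m)))
        msgs <- c(msgs, "matrix must be square with matching dimnames")
    else {
        if (max(abs(m - t(m))) > 1e-9)
            msgs <- c(msgs, "matrix must be symmetric (tol 1e-9)")
        if (any(abs(m) > 1 + 1e-9))
            msgs <- c(msgs, "correlations must lie in [-1, 1]")
        if (nrow(m) && max(abs(diag(m) - 1)) > 1e-9)
            msgs <- c(msgs, "diagonal must equal 1")
    }
    if (length(msgs)) msgs else TRUE
})

#' WeightedNetwork: thresholded co-occurrence network
#'
#' Symmetric non-negative weighted adjacency over an ordered taxon (node)
#' list; a weight of 0 means "no edge" and the diagonal is zero. Networks
#' built by [thresholdToNetwork()] only carry weights strictly greater than
#' the threshold used.
#'
#' @slot adj symmetric non-negative numeric matrix, zero diagonal, taxon
#'   dimnames.
#' @slot threshold the edge threshold the network was built with (`NA` when
#'   not applicable, e.g. contracted networks).
#' @aliases WeightedNetwork
#' @exportClass WeightedNetwork
setClass("WeightedNetwork",
    slots = c(adj = "matrix", threshold = "numeric"))

setValidity("WeightedNetwork", function(object) {
    m <- object@adj
    msgs <- character()
    tn <- .checkTaxaNames(rownames(m), "adjacency", nrow(m))
    if (!is.null(tn)) msgs <- c(msgs, tn)
    if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m)))
        msgs <- c(msgs, "adjacency must be square with matching dimnames")
    else {
        if (nrow(m) && max(abs(m - t(m))) > 1e-9)
            msgs <- c(msgs, "adjacency must be symmetric")
        if (any(m < 0))
            msgs <- c(msgs, "edge weights must be non-negative")
        if (nrow(m) && any(diag(m) != 0))
            msgs <- c(msgs, "diagonal must be zero (no self-edges)")
    }
    if (length(object@threshold) != 1L)
        msgs <- c(msgs, "threshold must be a single value (possibly NA)")
    if (length(msgs)) msgs else TRUE
})

#' @describeIn WeightedNetwork-class constructor
#' @param adj symmetric non-negative adjacency matrix with taxon dimnames.
#' @param threshold edge threshold used to build the network (`NA` if none).
#' @export
WeightedNetwork <- function(adj, threshold = NA_real_) {
    adj <- as.matrix(adj)
    adj <- (adj + t(adj)) / 2   # remove numeric asymmetry
    new("WeightedNetwork", adj = adj, threshold = as.numeric(threshold))
}

#' ContractionMap: partition of effective taxa into similar-bacteria groups
#'
#' Disjoint groups of taxa sharing the parent-level taxonomic category and the
#' same community in both groups' networks, each with one representative
#' (the member with the highest pooled mean relative abundance, chosen by
#' [chooseRepresentatives()]; `NA` until chosen).
#'
#' @slot members list of character vectors, one per group (a partition).
#' @slot representative character vector, one per group (may be `NA` before
#'   representatives are chosen).
#' @slot supCategory character vector, the shared parent-level name per group.
#' @aliases ContractionMap
#' @exportClass ContractionMap
setClass("ContractionMap",
    slots = c(members = "list", representative = "character",
              supCategory = "character"))

setValidity("ContractionMap", function(object) {
    msgs <- character()
    k <- length(object@members)
    if (length(object@representative) != k || length(object@supCategory) != k)
        msgs <- c(msgs, "members, representative and supCategory lengths differ")
    all_members <- unlist(object@members, use.names = FALSE)
    if (anyDuplicated(all_members))
        msgs <- c(msgs, "groups must be disjoint")
    if (any(lengths(object@members) < 1L))
        msgs <- c(msgs, "every group needs at least one member")
    ok <- is.na(object@representative) |
        mapply(function(r, mem) r %in% mem, object@representative,
               object@members)
    if (!all(ok))
        msgs <- c(msgs, "each representative must be one of its group's members")
    if (length(msgs)) msgs else TRUE
})

#' CoreSet: representatives significantly increased in the focus group
#'
#' Holds the one-sided Mann-Whitney p value of every representative taxon and
#' the subset ("core bacteria") with `p < pThreshold` in the focus group.
#'
#' @slot pValues named numeric vector of p values, one per representative.
#' @slot core character vector of core taxa (those with `p < pThreshold`).
#' @slot focus focus-group label (`"X"` or `"Y"`).
#' @slot pThreshold the significance threshold used (strict `<`).
#' @aliases CoreSet
#' @exportClass CoreSet
setClass("CoreSet",
    slots = c(pValues = "numeric", core = "character", focus = "character",
              pThreshold = "numeric"))

setValidity("CoreSet", function(object) {
    msgs <- character()
    p <- object@pValues
    if (length(p) && (is.null(names(p)) || anyNA(p) || any(p < 0 | p > 1)))
        msgs <- c(msgs, "pValues must be named and lie in [0, 1]")
    if (!all(object@core %in% names(p)))
        msgs <- c(msgs, "core taxa must be a subset of the tested representatives")
    if (length(object@core) && any(p[object@core] >= object@pThreshold))
        msgs <- c(msgs, "core taxa must satisfy p < pThreshold (strict)")
    if (!object@focus %in% c("X", "Y"))
        msgs <- c(msgs, "focus must be 'X' or 'Y'")
    if (length(msgs)) msgs else TRUE
})

#' SubnetworkPair: the core+neighbour networks G_X and G_Y
#'
#' The two networks restricted to the shared node set V (core taxa plus every
#' node adjacent to a core taxon in at least one network), indexed
#' identically.
#'
#' @slot nodes ordered character vector V.
#' @slot adjX,adjY symmetric weight matrices over `nodes`.
#' @aliases SubnetworkPair
#' @exportClass SubnetworkPair
setClass("SubnetworkPair",
    slots = c(nodes = "character", adjX = "matrix", adjY = "matrix"))

setValidity("SubnetworkPair", function(object) {
    msgs <- character()
    v <- object@nodes
    for (nm in c("adjX", "adjY")) {
        m <- slot(object, nm)
        if (length(v) == 0L) {
            if (nrow(m) != 0L || ncol(m) != 0L)
                msgs <- c(msgs, sprintf("%s must be 0x0 for an empty pair", nm))
            next
        }
        if (!identical(rownames(m), v) || !identical(colnames(m), v))
            msgs <- c(msgs, sprintf("%s dimnames must equal the node list", nm))
        else if (nrow(m) && max(abs(m - t(m))) > 1e-9)
            msgs <- c(msgs, sprintf("%s must be symmetric", nm))
    }
    if (length(msgs)) msgs else TRUE
})
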