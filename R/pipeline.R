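# End-to-end orchestration of Steps 0-5: normalisation, correlation networks,
# contraction, core selection, subnetwork construction and rewiring scores,
# with all outputs and a manifest written to a directory.

#' Configure a pipeline run
#'
#' Collects inputs and tuning parameters for [runPipeline()]. Count inputs may
#' be file paths (read with [readCountTable()]) or in-memory [CountTable]s;
#' the taxonomy a path or a named character vector.
#'
#' @param countsX,countsY per-group count tables (paths or [CountTable]s).
#' @param taxonomy genus-to-family mapping (path or named character vector).
#' @param outDir output directory (created if needed); `NULL` to skip writing.
#' @param focus which group the core-bacteria increase is tested in.
#' @param edgeThreshold correlation threshold for network edges, default 0.4.
#' @param pThreshold core-selection significance threshold, default 0.005.
#' @param seed integer seed driving the SparCC resampling and Louvain
#'   clustering.
#' @param backend correlation backend, see [estimateCorrelations()].
#' @param sparccIterations,sparccExclusionThreshold,sparccExclusionRounds,sparccPseudoCount
#'   SparCC parameters, see [sparccCorrelation()].
#' @param precomputedX,precomputedY correlation matrices (or paths) for the
#'   `"precomputed"` backend.
#' @param skipContraction bypass the similar-bacteria unification (Step 2);
#'   every effective taxon then represents itself.
#' @param contractMean contracted-edge weight mode, see [contractNetworks()].
#' @param unclassifiedLabels labels removed after normalisation, see
#'   [dropUnclassified()].
#' @return a list of class `QndConfig`.
#' @export
qndConfig <- function(countsX, countsY, taxonomy, outDir = NULL,
                      focus = c("Y", "X"), edgeThreshold = 0.4,
                      pThreshold = 0.005, seed = 42,
                      backend = c("sparcc", "spearman", "precomputed"),
                      sparccIterations = 20, sparccExclusionThreshold = 0.1,
                      sparccExclusionRounds = 10, sparccPseudoCount = 1,
                      precomputedX = NULL, precomputedY = NULL,
                      skipContraction = FALSE,
                      contractMean = c("edges", "all-pairs"),
                      unclassifiedLabels = c("unclassified", "unclassifed")) {
    cfg <- list(countsX = countsX, countsY = countsY, taxonomy = taxonomy,
                outDir = outDir, focus = match.arg(focus),
                edgeThreshold = edgeThreshold, pThreshold = pThreshold,
                seed = as.integer(seed), backend = match.arg(backend),
                sparccIterations = sparccIterations,
                sparccExclusionThreshold = sparccExclusionThreshold,
                sparccExclusionRounds = sparccExclusionRounds,
                sparccPseudoCount = sparccPseudoCount,
                precomputedX = precomputedX, precomputedY = precomputedY,
                skipContraction = isTRUE(skipContraction),
                contractMean = match.arg(contractMean),
                unclassifiedLabels = unclassifiedLabels)
    class(cfg) <- "QndConfig"
    cfg
}

.loadCounts <- function(x, group) {
    if (is(x, "CountTable")) x else readCountTable(x, group)
}

.loadTaxonomy <- function(x) {
    if (is.character(x) && length(x) == 1L && is.null(names(x)))
        readTaxonomy(x)
    else x
}

.loadPrecomputed <- function(x) {
    if (is.character(x) && length(x) == 1L) readCorrelationMatrix(x) else x
}

#' Run the full differential-rewiring pipeline
#'
#' Executes Steps 0-5 on two count tables: per-sample normalisation and
#' removal of unclassified taxa; correlation inference and thresholding into
#' two networks; joint-isolate pruning; Louvain clustering and
#' taxonomy-constrained contraction; one-sided Mann-Whitney core selection;
#' core+neighbour subnetwork construction; and QNetDiff scoring. When
#' `cfg$outDir` is set, writes `score_table.tsv`, `core_bacteria.tsv`,
#' `unified_groups.tsv`, edge lists and GraphML for the final subnetworks and
#' their per-edge difference network, and `manifest.json` (configuration +
#' seed) enabling identical re-runs. An empty core set is a warning, not an
#' error, and yields empty outputs.
#'
#' @param cfg a [qndConfig()].
#' @return (invisibly) a list with the intermediate and final objects:
#'   `abundX`, `abundY`, `netX`, `netY`, `effectiveTaxa`, `cmap`,
#'   `contractedX`, `contractedY`, `core`, `pair`, `scoreTable`.
#' @export
runPipeline <- function(cfg) {
    stopifnot(inherits(cfg, "QndConfig"))

    # Step 0: load, normalise, drop unclassified
    ctX <- .loadCounts(cfg$countsX, "X")
    ctY <- .loadCounts(cfg$countsY, "Y")
    overlap <- intersect(sampleIDs(ctX), sampleIDs(ctY))
    if (length(overlap))
        warning("sample IDs occur in both groups (possible user error): ",
                paste(utils::head(overlap, 5L), collapse = ", "))
    taxonomy <- .loadTaxonomy(cfg$taxonomy)
    if (!identical(taxa(ctX), taxa(ctY)))
        stop("Step 0: the two count tables must list the same taxa in the ",
             "same order")
    atX <- dropUnclassified(toRelativeAbundance(ctX), cfg$unclassifiedLabels)
    atY <- dropUnclassified(toRelativeAbundance(ctY), cfg$unclassifiedLabels)
    kept <- taxa(atX)
    ctX <- CountTable(counts(ctX)[kept, , drop = FALSE], "X")
    ctY <- CountTable(counts(ctY)[kept, , drop = FALSE], "Y")
    checkTaxonomyCovers(taxonomy, kept)

    # Step 1: correlations -> thresholded networks -> joint-isolate pruning
    corX <- estimateCorrelations(ctX, backend = cfg$backend, seed = cfg$seed,
        iterations = cfg$sparccIterations,
        exclusionThreshold = cfg$sparccExclusionThreshold,
        exclusionRounds = cfg$sparccExclusionRounds,
        pseudoCount = cfg$sparccPseudoCount,
        precomputed = .loadPrecomputed(cfg$precomputedX))
    corY <- estimateCorrelations(ctY, backend = cfg$backend,
        seed = cfg$seed + 1L,
        iterations = cfg$sparccIterations,
        exclusionThreshold = cfg$sparccExclusionThreshold,
        exclusionRounds = cfg$sparccExclusionRounds,
        pseudoCount = cfg$sparccPseudoCount,
        precomputed = .loadPrecomputed(cfg$precomputedY))
    netX <- thresholdToNetwork(corX, cfg$edgeThreshold)
    netY <- thresholdToNetwork(corY, cfg$edgeThreshold)
    pruned <- pruneJointlyIsolated(netX, netY)
    eff <- pruned$effectiveTaxa

    # Step 2: cluster, unify similar bacteria, choose representatives,
    # contract (or the identity contraction when skipped)
    if (length(eff) == 0L) {
        cmap <- identityContraction(character(), taxonomy)
        conX <- pruned$netX
        conY <- pruned$netY
    } else if (cfg$skipContraction) {
        cmap <- identityContraction(eff, taxonomy)
        conX <- pruned$netX
        conY <- pruned$netY
    } else {
        clX <- clusterNodes(pruned$netX, seed = cfg$seed)
        clY <- clusterNodes(pruned$netY, seed = cfg$seed)
        cmap <- findSimilarGroups(taxonomy, clX, clY)
        cmap <- chooseRepresentatives(cmap, atX, atY)
        conX <- contractNetworks(pruned$netX, cmap, mode = cfg$contractMean)
        conY <- contractNetworks(pruned$netY, cmap, mode = cfg$contractMean)
    }

    # Step 3: core bacteria
    core <- if (length(cmap@members))
        selectCore(cmap, atX, atY, focus = cfg$focus,
                   pThreshold = cfg$pThreshold)
    else new("CoreSet", pValues = stats::setNames(numeric(), character()),
             core = character(), focus = cfg$focus,
             pThreshold = cfg$pThreshold)
    if (length(coreTaxa(core)) == 0L)
        warning("no representative passed p < ", cfg$pThreshold,
                " in group ", cfg$focus, "; outputs will be empty")

    # Steps 4-5: subnetwork pair and rewiring scores
    pair <- buildCoreSubnetworks(conX, conY, core)
    scoreTable <- featureTable(pair, atX, atY, core)

    res <- list(abundX = atX, abundY = atY, netX = pruned$netX,
                netY = pruned$netY, effectiveTaxa = eff, cmap = cmap,
                contractedX = conX, contractedY = conY, core = core,
                pair = pair, scoreTable = scoreTable)

    if (!is.null(cfg$outDir)) .writeOutputs(res, cfg)
    invisible(res)
}

.writeOutputs <- function(res, cfg) {
    dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(cfg$outDir, f)
    utils::write.table(res$scoreTable, out("score_table.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    coreTable(res$core, out("core_bacteria.tsv"))
    contractionTable(res$cmap, out("unified_groups.tsv"))
    gx <- WeightedNetwork(res$pair@adjX)
    gy <- WeightedNetwork(res$pair@adjY)
    edgeList(gx, out("subnetwork_X_edges.tsv"))
    edgeList(gy, out("subnetwork_Y_edges.tsv"))
    edgeList(differenceNetwork(res$pair), out("difference_edges.tsv"))
    if (length(res$pair@nodes)) {
        writeGraphML(gx, out("subnetwork_X.graphml"))
        writeGraphML(gy, out("subnetwork_Y.graphml"))
        writeGraphML(differenceNetwork(res$pair),
                     out("difference_network.graphml"))
    }
    manifest <- cfg
    manifest$countsX <- if (is.character(cfg$countsX)) cfg$countsX
                        else "<in-memory CountTable>"
    manifest$countsY <- if (is.character(cfg$countsY)) cfg$countsY
                        else "<in-memory CountTable>"
    manifest$taxonomy <- if (is.character(cfg$taxonomy) &&
                             is.null(names(cfg$taxonomy))) cfg$taxonomy
                         else "<in-memory taxonomy>"
    manifest$precomputedX <- manifest$precomputedY <- NULL
    manifest <- c(unclass(manifest),
                  list(package = "qnetdiff",
                       version = as.character(utils::packageVersion("qnetdiff")),
                       rversion = as.character(getRversion())))
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
    invisible(cfg$outDir)
}
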