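# Synthetic paired count tables with the statistical structure the method
# assumes: compositional counts from latent log-normal basis abundances, a
# sibling set of genera produced by multinomially splitting one latent taxon
# (the multi-mapping artifact behind false correlations), planted
# differential abundance in group Y, and one planted rewiring taxon whose
# co-occurrence partners switch between the groups.

#' Specify a synthetic fixture
#'
#' Defaults describe a small but realistic two-group study: 40 genera,
#' 60 samples per group, sequencing depth uniform in 20k-50k, a 4-fold planted
#' increase, 4 co-occurrence partners on each side of the rewiring taxon and
#' one sibling set of 3 genera with near-equal multinomial shares.
#'
#' The planted rewiring taxon is itself differentially increased, so it is
#' selected as a core taxon and the final subnetwork is built around it (core
#' taxa are the anchors of Steps 4-5). A second differential taxon comes with
#' a stable co-occurrence companion so that it stays an effective (connected)
#' node in both networks.
#'
#' @param nTaxa number of observed genera.
#' @param nSamplesX,nSamplesY samples per group.
#' @param depthRange integer range for per-sample sequencing depth.
#' @param foldChange multiplicative increase of planted differential taxa in
#'   group Y.
#' @param nPartners size of each of the rewiring taxon's partner sets S (in X)
#'   and T (in Y).
#' @param siblingSize number of sibling genera split from one latent taxon
#'   (>= 2).
#' @param siblingShares multinomial shares of the sibling split (recycled /
#'   normalised to `siblingSize`).
#' @param factorCorrelation target log-scale correlation within planted
#'   co-occurrence modules.
#' @param baselineSdLog log-scale standard deviation of unplanted taxa.
#' @param plantSiblings,plantDifferential,plantRewiring switch each planted
#'   structure off for null fixtures.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return a list of class `FixtureSpec`.
#' @export
fixtureSpec <- function(nTaxa = 40, nSamplesX = 60, nSamplesY = 60,
                        depthRange = c(20000L, 50000L), foldChange = 4,
                        nPartners = 4, siblingSize = 3,
                        siblingShares = c(0.40, 0.35, 0.25),
                        factorCorrelation = 0.9, baselineSdLog = 1,
                        plantSiblings = TRUE, plantDifferential = TRUE,
                        plantRewiring = TRUE, seed = 1) {
    spec <- list(nTaxa = as.integer(nTaxa), nSamplesX = as.integer(nSamplesX),
                 nSamplesY = as.integer(nSamplesY),
                 depthRange = as.integer(depthRange),
                 foldChange = foldChange, nPartners = as.integer(nPartners),
                 siblingSize = as.integer(siblingSize),
                 siblingShares = siblingShares,
                 factorCorrelation = factorCorrelation,
                 baselineSdLog = baselineSdLog,
                 plantSiblings = isTRUE(plantSiblings),
                 plantDifferential = isTRUE(plantDifferential),
                 plantRewiring = isTRUE(plantRewiring),
                 seed = as.integer(seed))
    class(spec) <- "FixtureSpec"
    spec
}

#' Generate a paired synthetic fixture
#'
#' Draws the two count tables, the genus-to-family taxonomy and the ground
#' truth of all planted structure from a [fixtureSpec()]. All randomness is
#' governed by `spec$seed`; the same spec yields byte-identical tables.
#'
#' @param spec a [fixtureSpec()].
#' @return list with elements `countsX`, `countsY` ([CountTable]s),
#'   `taxonomy` (named character vector, genus -> family) and `truth`
#'   (list recording planted labels).
#' @export
generateFixture <- function(spec) {
    stopifnot(inherits(spec, "FixtureSpec"))
    if (spec$siblingSize < 2L && spec$plantSiblings)
        stop("a sibling set needs at least 2 members")
    nPlanted <- (if (spec$plantRewiring) 1L + 2L * spec$nPartners else 0L) +
        (if (spec$plantDifferential) 2L else 0L) +
        (if (spec$plantSiblings) spec$siblingSize else 0L)
    if (nPlanted > spec$nTaxa)
        stop("infeasible spec: ", nPlanted, " planted taxa but only ",
             spec$nTaxa, " taxa")

    tx <- sprintf("Genus%03d", seq_len(spec$nTaxa))
    fam <- stats::setNames(sprintf("Family%03d", seq_len(spec$nTaxa)), tx)

    idx <- 0L
    take <- function(n) { out <- idx + seq_len(n); idx <<- idx + n; tx[out] }
    rewire <- partnersX <- partnersY <- character()
    if (spec$plantRewiring) {
        rewire <- take(1L)
        partnersX <- take(spec$nPartners)
        partnersY <- take(spec$nPartners)
    }
    diffExtra <- companion <- character()
    if (spec$plantDifferential) {
        diffExtra <- take(1L)
        companion <- take(1L)
    }
    siblings <- character()
    if (spec$plantSiblings) {
        siblings <- take(spec$siblingSize)
        fam[siblings] <- "FamilySib"
    }
    differential <- if (spec$plantDifferential) c(rewire, diffExtra)
                    else character()

    # latent taxa: observed minus siblings, plus one latent sibling source
    latent <- setdiff(tx, siblings)
    if (spec$plantSiblings) latent <- c(latent, ".sibLatent")
    D <- length(latent)

    mu <- NULL
    shares <- rep(spec$siblingShares, length.out = spec$siblingSize)
    shares <- shares / sum(shares)
    # within-module noise sd giving the target log-scale correlation for a
    # unit-variance shared factor: rho = 1 / (1 + s^2)
    sNoise <- sqrt(1 / spec$factorCorrelation - 1)

    drawGroup <- function(n, group) {
        logA <- matrix(mu, D, n) # baseline means
        rownames(logA) <- latent
        fX <- stats::rnorm(n); fY <- stats::rnorm(n); fD <- stats::rnorm(n)
        for (i in latent) {
            loads <- 0
            inModule <- FALSE
            if (spec$plantRewiring) {
                if (i == rewire) { loads <- if (group == "X") fX else fY
                                   inModule <- TRUE }
                else if (i %in% partnersX) { loads <- fX; inModule <- TRUE }
                else if (i %in% partnersY) { loads <- fY; inModule <- TRUE }
            }
            if (spec$plantDifferential && i %in% c(diffExtra, companion)) {
                loads <- fD; inModule <- TRUE
            }
            sdE <- if (inModule) sNoise else spec$baselineSdLog
            logA[i, ] <- logA[i, ] + loads + stats::rnorm(n, 0, sdE)
        }
        if (group == "Y" && spec$plantDifferential)
            logA[differential, ] <- logA[differential, ] +
                log(spec$foldChange)
        comp <- exp(logA)
        comp <- sweep(comp, 2L, colSums(comp), "/")
        depth <- sample(seq(spec$depthRange[1L], spec$depthRange[2L]), n,
                        replace = TRUE)
        cnt <- vapply(seq_len(n),
                      function(k) stats::rmultinom(1L, depth[k], comp[, k])[, 1L],
                      numeric(D))
        rownames(cnt) <- latent
        obs <- matrix(0, spec$nTaxa, n, dimnames = list(tx, NULL))
        obs[setdiff(tx, siblings), ] <- cnt[setdiff(tx, siblings), ]
        if (spec$plantSiblings) {
            for (k in seq_len(n))
                obs[siblings, k] <- stats::rmultinom(
                    1L, cnt[".sibLatent", k], shares)[, 1L]
        }
        colnames(obs) <- sprintf("%s%03d", group, seq_len(n))
        CountTable(obs, group)
    }

    res <- withSeed(spec$seed, {
        mu <- stats::rnorm(D, 0, 1)
        names(mu) <- latent
        planted <- c(rewire, partnersX, partnersY, differential, companion,
                     if (spec$plantSiblings) ".sibLatent")
        # planted taxa get at-least-average baseline abundance so planted
        # structure is identifiable at realistic sequencing depth
        mu[intersect(planted, latent)] <-
            pmax(mu[intersect(planted, latent)], 0)
        list(X = drawGroup(spec$nSamplesX, "X"),
             Y = drawGroup(spec$nSamplesY, "Y"))
    })

    truth <- list(
        rewiringTaxon = rewire, partnersX = partnersX, partnersY = partnersY,
        differentialTaxa = differential, siblingSet = siblings,
        siblingExpectedRepresentative =
            if (length(siblings)) siblings[which.max(shares)] else character(),
        foldChange = spec$foldChange, seed = spec$seed)
    list(countsX = res$X, countsY = res$Y, taxonomy = fam, truth = truth)
}

#' Write a fixture to disk
#'
#' Emits the TSV dialects the readers expect (`counts_X.tsv`, `counts_Y.tsv`,
#' `taxonomy.tsv`) plus the ground truth as `ground_truth.json`.
#'
#' @param fix result of [generateFixture()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeFixture <- function(fix, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeCountTable(fix$countsX, file.path(dir, "counts_X.tsv"))
    writeCountTable(fix$countsY, file.path(dir, "counts_Y.tsv"))
    utils::write.table(
        data.frame(taxon = names(fix$taxonomy),
                   sup_category = unname(fix$taxonomy)),
        file.path(dir, "taxonomy.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    jsonlite::write_json(fix$truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(dir)
}

#' Simulate independent (or pairwise-correlated) compositional counts
#'
#' Null model for correlation-inference checks: latent basis abundances are
#' independent log-normals; optionally one pair of taxa is given a planted
#' log-scale basis correlation. Counts are multinomial draws at a uniform
#' random depth per sample.
#'
#' @param nTaxa,nSamples table dimensions.
#' @param depthRange integer depth range.
#' @param plantedRho optional basis correlation planted between the first two
#'   taxa (`NULL` for a fully independent table).
#' @param sdLog log-scale standard deviation of the basis abundances.
#' @param seed integer seed.
#' @return a [CountTable] (group `"X"`).
#' @export
simulateCompositionalCounts <- function(nTaxa = 20, nSamples = 200,
                                        depthRange = c(20000L, 50000L),
                                        plantedRho = NULL, sdLog = 1,
                                        seed = 1) {
    tx <- sprintf("Genus%03d", seq_len(nTaxa))
    withSeed(seed, {
        mu <- stats::rnorm(nTaxa, 0, 1)
        z <- matrix(stats::rnorm(nTaxa * nSamples, 0, sdLog), nTaxa, nSamples)
        if (!is.null(plantedRho)) {
            stopifnot(nTaxa >= 2, abs(plantedRho) <= 1)
            z[2L, ] <- plantedRho * z[1L, ] +
                sqrt(1 - plantedRho^2) * z[2L, ]
        }
        logA <- mu + z
        comp <- exp(logA)
        comp <- sweep(comp, 2L, colSums(comp), "/")
        depth <- sample(seq(depthRange[1L], depthRange[2L]), nSamples,
                        replace = TRUE)
        cnt <- vapply(seq_len(nSamples),
                      function(k) stats::rmultinom(1L, depth[k], comp[, k])[, 1L],
                      numeric(nTaxa))
        rownames(cnt) <- tx
        colnames(cnt) <- sprintf("S%03d", seq_len(nSamples))
        CountTable(cnt, "X")
    })
}
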