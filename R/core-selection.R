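# Step 3: representatives significantly increased in the focus group become
# "core bacteria". A raw per-taxon threshold (default 0.005) is applied, no
# multiple-testing correction, matching the method's contract.

#' One-sided Mann-Whitney U test
#'
#' p value for the alternative "values in `y` are stochastically greater than
#' in `x`". The exact null distribution is used when both samples are tie-free
#' and the smaller one has at most `exactLimit` observations; otherwise the
#' tie-corrected normal approximation (with continuity correction) is used.
#' Thin wrapper around [stats::wilcox.test()].
#'
#' @param x,y nonempty numeric vectors.
#' @param exactLimit largest min-sample-size for which the exact distribution
#'   is enumerated.
#' @return the one-sided p value.
#' @export
mannWhitneyOneSided <- function(x, y, exactLimit = 8) {
    if (!length(x) || !length(y))
        stop("both sample vectors must be nonempty")
    ties <- anyDuplicated(c(x, y)) > 0L
    exact <- !ties && min(length(x), length(y)) <= exactLimit
    suppressWarnings(
        stats::wilcox.test(y, x, alternative = "greater", exact = exact,
                           correct = TRUE)$p.value)
}

#' Select core bacteria
#'
#' Tests every representative taxon's relative abundance for an increase in
#' the focus group (one-sided Mann-Whitney U on the per-sample relative
#' abundances; counts are not comparable across samples of differing depth).
#' Representatives with `p < pThreshold` (strict) form the core set; all p
#' values are retained for the output feature table.
#'
#' @param cmap a [ContractionMap] with representatives chosen.
#' @param atX,atY [AbundanceTable]s for groups X and Y.
#' @param focus which group the increase is tested in (`"X"` or `"Y"`).
#' @param pThreshold significance threshold, default 0.005.
#' @param exactLimit passed to [mannWhitneyOneSided()].
#' @return a [CoreSet].
#' @export
selectCore <- function(cmap, atX, atY, focus = c("Y", "X"),
                       pThreshold = 0.005, exactLimit = 8) {
    stopifnot(is(cmap, "ContractionMap"), is(atX, "AbundanceTable"),
              is(atY, "AbundanceTable"))
    focus <- match.arg(focus)
    if (!is.numeric(pThreshold) || length(pThreshold) != 1L ||
        is.na(pThreshold) || pThreshold <= 0 || pThreshold > 1)
        stop("pThreshold must be a single value in (0, 1]")
    reps <- cmap@representative
    if (anyNA(reps))
        stop("representatives must be chosen before core selection")
    p <- vapply(reps, function(r) {
        vx <- atX@abund[r, ]
        vy <- atY@abund[r, ]
        if (focus == "Y") mannWhitneyOneSided(vx, vy, exactLimit)
        else mannWhitneyOneSided(vy, vx, exactLimit)
    }, 1.0)
    names(p) <- reps
    new("CoreSet", pValues = p, core = reps[p < pThreshold], focus = focus,
        pThreshold = pThreshold)
}

#' Tabulate core selection results
#'
#' One row per representative with its p value and an `is_core` flag.
#'
#' @param core a [CoreSet].
#' @param path optional TSV output path.
#' @return data.frame sorted by p value.
#' @export
coreTable <- function(core, path = NULL) {
    stopifnot(is(core, "CoreSet"))
    df <- data.frame(
        taxon = names(core@pValues),
        p_value = unname(core@pValues),
        is_core = names(core@pValues) %in% core@core,
        stringsAsFactors = FALSE)
    df <- df[order(df$p_value, df$taxon), , drop = FALSE]
    rownames(df) <- NULL
    if (!is.null(path))
        utils::write.table(df, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    df
}
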