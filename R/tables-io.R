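#' Read a genus-by-sample count table
#'
#' Expects a UTF-8 tab-delimited file with sample IDs in the header row and
#' taxon names in the first column. Counts must be non-negative integers;
#' duplicate taxon names and malformed cells are rejected with an error that
#' names the offending row/column.
#'
#' @param path path to the TSV file.
#' @param group group label to attach (e.g. `"X"` or `"Y"`).
#' @return a [CountTable].
#' @seealso [writeCountTable()], [toRelativeAbundance()]
#' @export
readCountTable <- function(path, group) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE,
                            quote = "", comment.char = "")
    if (ncol(df) < 3L)
        stop("count table '", path, "' needs a taxon column and >= 2 samples")
    taxa <- as.character(df[[1L]])
    dup <- taxa[duplicated(taxa)]
    if (length(dup))
        stop("duplicate taxon names in '", path, "': ",
             paste(unique(dup), collapse = ", "))
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m) || anyNA(m)) {
        bad <- which(is.na(suppressWarnings(
            matrix(as.numeric(m), nrow(m)))), arr.ind = TRUE)
        loc <- if (nrow(bad)) sprintf(" (e.g. taxon '%s', sample '%s')",
                                      taxa[bad[1, 1]], colnames(m)[bad[1, 2]])
               else ""
        stop("non-numeric counts in '", path, "'", loc)
    }
    neg <- which(m < 0, arr.ind = TRUE)
    if (nrow(neg))
        stop(sprintf("negative count in '%s' at taxon '%s', sample '%s'",
                     path, taxa[neg[1, 1]], colnames(m)[neg[1, 2]]))
    frac <- which(abs(m - round(m)) > 1e-8, arr.ind = TRUE)
    if (nrow(frac))
        stop(sprintf("non-integer count in '%s' at taxon '%s', sample '%s'",
                     path, taxa[frac[1, 1]], colnames(m)[frac[1, 2]]))
    rownames(m) <- taxa
    CountTable(m, group)
}

#' Write a CountTable as TSV
#'
#' Inverse of [readCountTable()]: first column `taxon`, remaining columns the
#' sample IDs.
#'
#' @param ct a [CountTable].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeCountTable <- function(ct, path) {
    stopifnot(is(ct, "CountTable"))
    df <- data.frame(taxon = taxa(ct), ct@counts, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a taxonomy (parent-level annotation) table
#'
#' Two-column tab-delimited file with header `taxon<TAB>sup_category` mapping
#' each taxon name to its parent-level name (e.g. genus to family).
#'
#' @param path path to the TSV file.
#' @return named character vector: `taxonomy[taxon] == sup_category`.
#' @export
readTaxonomy <- function(path) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE,
                            quote = "", comment.char = "")
    if (ncol(df) < 2L)
        stop("taxonomy '", path, "' needs two columns: taxon, sup_category")
    taxon <- as.character(df[[1L]])
    if (anyDuplicated(taxon))
        stop("duplicate taxa in taxonomy '", path, "': ",
             paste(unique(taxon[duplicated(taxon)]), collapse = ", "))
    stats::setNames(as.character(df[[2L]]), taxon)
}

#' Check that a taxonomy covers a set of taxa
#'
#' @param taxonomy named character vector from [readTaxonomy()].
#' @param taxaNames character vector of taxon names that will be queried.
#' @return the taxonomy, invisibly; errors listing any missing taxa.
#' @export
checkTaxonomyCovers <- function(taxonomy, taxaNames) {
    missing <- setdiff(taxaNames, names(taxonomy))
    if (length(missing))
        stop("taxa present in counts but absent from taxonomy: ",
             paste(missing, collapse = ", "))
    invisible(taxonomy)
}

#' Convert counts to relative abundance
#'
#' Per-sample closure: `abundance[i, k] = count[i, k] / sum_h count[h, k]`,
#' so every sample column sums to 1. Sequencing depth differs between
#' samples, so counts are only comparable after this normalisation.
#'
#' @param ct a [CountTable].
#' @return an [AbundanceTable] with the same dimnames and group label.
#' @export
toRelativeAbundance <- function(ct) {
    stopifnot(is(ct, "CountTable"))
    tot <- colSums(ct@counts)
    zero <- names(tot)[tot == 0]
    if (length(zero))
        stop("all-zero sample column(s): ", paste(zero, collapse = ", "),
             " - cannot normalise to relative abundance")
    new("AbundanceTable", abund = sweep(ct@counts, 2L, tot, "/"),
        group = ct@group)
}

#' Remove unclassified taxa after normalisation
#'
#' Drops rows whose taxon name matches one of `labels` (case-insensitively).
#' This happens after normalisation, so the remaining relative abundances are
#' unchanged and sample columns may then sum to less than 1. The default label
#' list also covers the common misspelling "unclassifed" seen in annotation
#' output.
#'
#' @param at an [AbundanceTable].
#' @param labels character vector of labels to drop (case-insensitive).
#' @return an [AbundanceTable] without the matching rows; a no-op when no row
#'   matches.
#' @export
dropUnclassified <- function(at, labels = c("unclassified", "unclassifed")) {
    stopifnot(is(at, "AbundanceTable"))
    keep <- !(tolower(taxa(at)) %in% tolower(labels))
    if (all(keep)) return(at)
    new("AbundanceTable", abund = at@abund[keep, , drop = FALSE],
        group = at@group)
}
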