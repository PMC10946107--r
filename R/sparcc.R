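# Compositionally aware basis-correlation inference (Friedman-Alm scheme).
#
# Counts are compositional: per-sample closure induces spurious negative
# correlations when Pearson/Spearman is applied to fractions. The scheme
# estimates correlations between the latent ("basis") abundances from
# pairwise log-ratio variances:
#   t_ij = Var(log x_i - log x_j) = w_i + w_j - 2 r_ij sqrt(w_i w_j)
# Under sparsity (most r_ij ~ 0) the basis variances w solve the linear
# system M w = rowSums(T), with M = 1 + diag(D - 2). Strongly correlated
# pairs violate the sparsity assumption and are iteratively excluded from
# the system. Fractions are resampled from a Dirichlet posterior per sample
# (counts + pseudo-count) and estimates averaged over inner iterations.

.dirichletFractions <- function(counts, pseudoCount) {
    d <- dim(counts)
    g <- matrix(stats::rgamma(prod(d), shape = counts + pseudoCount),
                d[1L], d[2L])
    sweep(g, 2L, colSums(g), "/")
}

# one inner iteration: log-ratio variance matrix -> basis correlations
.basisCorrelations <- function(logFrac, exclusionThreshold, exclusionRounds) {
    D <- nrow(logFrac)
    S <- stats::cov(t(logFrac))
    v <- diag(S)
    Tmat <- outer(v, rep(1, D)) + outer(rep(1, D), v) - 2 * S
    diag(Tmat) <- 0

    keep <- matrix(TRUE, D, D)      # pairs still feeding the sparsity system
    diag(keep) <- FALSE
    M <- matrix(1, D, D)
    diag(M) <- D - 1

    solveCorr <- function() {
        w <- solve(M, rowSums(Tmat * keep))
        w <- pmax(w, 1e-10)
        r <- (outer(w, rep(1, D)) + outer(rep(1, D), w) - Tmat) /
            (2 * sqrt(outer(w, w)))
        r[r > 1] <- 1
        r[r < -1] <- -1
        diag(r) <- 1
        r
    }

    r <- solveCorr()
    for (round in seq_len(exclusionRounds)) {
        a <- abs(r)
        a[!keep] <- 0
        mx <- max(a)
        if (mx <= exclusionThreshold) break
        ij <- which(a == mx, arr.ind = TRUE)[1L, ]
        i <- ij[1L]; j <- ij[2L]
        # keep each node in the system with at least 2 partners
        if (sum(keep[i, ]) <= 2L || sum(keep[j, ]) <= 2L) break
        keep[i, j] <- keep[j, i] <- FALSE
        M[i, j] <- M[j, i] <- 0
        M[i, i] <- M[i, i] - 1
        M[j, j] <- M[j, j] - 1
        r <- solveCorr()
    }
    r
}

#' SparCC-style basis correlations from a count matrix
#'
#' Low-level engine behind `estimateCorrelations(backend = "sparcc")`.
#' Resamples per-sample fractions from a Dirichlet posterior, estimates basis
#' correlations from pairwise log-ratio variances under a sparsity assumption
#' with iterative exclusion of the most correlated pair, and averages the
#' estimates over the inner iterations. Seeded and deterministic.
#'
#' @param countMatrix taxa-by-samples matrix of non-negative integer counts;
#'   at least 3 taxa (the log-ratio system is degenerate below that).
#' @param iterations number of Dirichlet resampling iterations to average.
#' @param exclusionThreshold pairs with `|r|` above this are excluded from the
#'   sparsity system.
#' @param exclusionRounds maximum number of exclusion rounds per iteration.
#' @param pseudoCount added to every count before Dirichlet sampling (log of
#'   zero is undefined otherwise).
#' @param seed integer seed controlling the resampling.
#' @return symmetric correlation matrix with unit diagonal.
#' @references Friedman J, Alm EJ (2012) Inferring correlation networks from
#'   genomic survey data. PLoS Comput Biol 8:e1002687.
#' @export
sparccCorrelation <- function(countMatrix, iterations = 20,
                              exclusionThreshold = 0.1, exclusionRounds = 10,
                              pseudoCount = 1, seed = 1) {
    countMatrix <- as.matrix(countMatrix)
    D <- nrow(countMatrix)
    if (D < 3L)
        stop("sparcc needs at least 3 taxa; its log-ratio system is ",
             "degenerate below that")
    if (ncol(countMatrix) < 2L)
        stop("sparcc needs at least 2 samples")
    allZero <- rownames(countMatrix)[rowSums(countMatrix) == 0]
    if (length(allZero))
        stop("taxa with zero counts in every sample: ",
             paste(allZero, collapse = ", "),
             " - add a pseudo-count upstream or remove them before sparcc")
    acc <- matrix(0, D, D)
    withSeed(seed, {
        for (it in seq_len(iterations)) {
            f <- .dirichletFractions(countMatrix, pseudoCount)
            acc <- acc + .basisCorrelations(log(f), exclusionThreshold,
                                            exclusionRounds)
        }
    })
    r <- acc / iterations
    r <- (r + t(r)) / 2
    r[r > 1] <- 1
    r[r < -1] <- -1
    diag(r) <- 1
    dimnames(r) <- list(rownames(countMatrix), rownames(countMatrix))
    r
}

# evaluate expr under a temporary RNG state; global stream untouched
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    eval.parent(substitute(expr))
}
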