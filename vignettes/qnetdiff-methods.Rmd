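---
title: "qnetdiff: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{qnetdiff: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qnetdiff)
```

# The question the method answers

Two-group microbiome comparisons usually rank taxa by differential
abundance. A complementary signal is *rewiring*: a taxon keeping a similar
abundance but exchanging its co-occurrence partners between conditions.
qnetdiff quantifies rewiring per taxon as the edge-weighted symmetric
difference between the taxon's incident edges in the two group networks, and
embeds that score in a pipeline that first protects it against the two main
artifacts of genus-level co-occurrence analysis: compositionality and
multi-mapped reads.

# The pipeline and its assumptions

## Normalisation (Step 0)

Counts are closed to relative abundances per sample. Rows labelled
"unclassified" (case-insensitive; the misspelling "unclassifed" produced by
some annotation tools is also matched) are removed *after* closure, so the
remaining abundances are unchanged and columns may sum to less than 1.
Removing before closure would inflate every other taxon; the order is
therefore fixed and covered by a regression test. All-zero sample columns
are an error, not a silent drop — they indicate an upstream problem the user
should see. No depth filter is applied; if very low-depth samples should be
excluded, exclude them upstream.

## Correlation networks (Step 1)

Relative abundances are compositional, so naive correlations are biased
negative. The default backend re-implements the log-ratio-variance
basis-correlation scheme (SparCC): per-sample fractions are drawn from a
Dirichlet posterior (counts + pseudo-count 1), pairwise log-ratio variances
`t_ij = Var(log x_i / x_j)` are converted to basis variances by solving the
sparsity-assumption linear system, and strongly correlated pairs
(`|r| > 0.1`) are iteratively excluded from that system (up to 10 rounds,
keeping every taxon with at least two partners in the system). Estimates are
averaged over 20 Dirichlet resampling iterations; averaging (rather than a
median) was chosen as the simpler estimator, and the downstream thresholding
is insensitive to the difference at these iteration counts. The whole
procedure is driven by one integer seed and restores the caller's RNG
stream.

The estimator assumes (i) most taxon pairs are uncorrelated (sparsity) and
(ii) at least 3 taxa. A taxon with zero counts in every sample makes the
log-ratios degenerate and is reported as an error with the fix spelled out
(pseudo-count or removal). A deterministic Spearman backend (on relative
abundances — rank correlation is depth-invariant only after closure) and a
precomputed-matrix backend are provided for users who want to slot in their
own estimator.

Correlations strictly greater than `edgeThreshold` (default 0.4, the
conventional cutoff for microbial co-occurrence networks) become edge
weights; ties at the threshold and all negative correlations are dropped —
the method looks for co-occurrence, not exclusion, so no absolute-value
option is offered. Taxa isolated in *both* networks are removed; a taxon
with an edge in either network is kept in both so the two adjacency
matrices stay index-compatible.

## Contraction of similar taxa (Step 2)

Reads that map equally well to several closely related genera are split
among them, making those genera spuriously correlated (≈ 1) and giving each
of them an inflated degree. The remedy is to unify such groups: each network
is clustered with the Louvain method (igraph, weighted modularity, fixed
seed), and the similar-bacteria groups are the equivalence classes of the
key *(family, cluster in X, cluster in Y)*. Working with equivalence classes
makes maximality automatic and the result order-independent. A pairwise
"must share an edge" requirement was deliberately *not* added on top: the
two formal conditions are the testable contract, and Louvain co-membership
of strongly correlated siblings implies connectivity in practice anyway.

Each group is represented by its member with the highest mean relative
abundance over the *pooled* samples of both groups (pooling keeps the choice
symmetric in X and Y; ties break lexicographically by name so runs are
reproducible). The contracted edge weight between two groups is the mean of
the *existing* inter-group edge weights, 0 when there is none. Averaging
over all member pairs instead would dilute genuine supra-threshold
correlations with structural zeros; since both readings are defensible, the
all-pairs variant is exposed as `contractMean = "all-pairs"`. A corollary of
the default is that every nonzero contracted weight stays above the edge
threshold (it is a mean of values that each exceed it) — this invariant is
tested. `skipContraction = TRUE` bypasses Step 2 entirely (useful when the
annotation has no reliable parent level); when every taxon has a distinct
family the two code paths provably coincide, which the suite exercises as a
consistency oracle.

## Core selection (Step 3)

Each representative is tested for increased relative abundance in the focus
group with a one-sided Mann–Whitney U test. The exact distribution is used
when both samples are tie-free and the smaller has at most 8 observations
(`exactLimit`, configurable); otherwise the tie-corrected normal
approximation with continuity correction. At typical study sizes (tens of
samples per group) the approximation is what runs; the exact path exists so
small pilot data are handled honestly, and it is verified against exhaustive
permutation enumeration. Representatives with `p < pThreshold` (default
0.005, strict inequality) are the core bacteria. No multiple-testing
correction is applied: the raw per-taxon threshold is the method's contract,
and the p values of *all* representatives are carried into the output so
users can apply their own correction downstream.

## Subnetworks and the rewiring index (Steps 4–5)

`V` collects the core taxa and every node adjacent to a core taxon in at
least one contracted network; both adjacencies are restricted to edges with
both ends in `V`. For each node the intersection size
`Σ_w min(A_X[v,w], A_Y[v,w])` and union size `Σ_w max(...)` are summed over
the union neighbourhood — equivalently over all nodes, since absent edges
weigh 0, which is why the sum needs no explicit neighbourhood bookkeeping —
and the score is their difference. Pointwise `max − min = |difference|`, so
the score equals the per-node L1 distance between adjacency rows; the suite
asserts this identity to 1e-12 on random graph pairs, along with symmetry
in the two networks, zero-iff-equal rows, the per-node triangle inequality,
and the reduction to neighbour-set symmetric-difference cardinality on 0/1
networks. Degree is reported separately per network (two columns rather
than one, so either convention is recoverable). An empty core set is legal:
the run warns and writes empty, parseable outputs with exit status 0.

# The synthetic fixture generator

Real two-group data with known rewiring ground truth do not exist, so the
generator plants the structure the method is built to detect into an
otherwise realistic compositional model:

- latent per-taxon log-normal basis abundances (log-scale SD 1);
- per-sample sequencing depth uniform in 20,000–50,000 and multinomial
  count sampling;
- one *sibling trio* produced by multinomially splitting a single latent
  genus with shares 0.40/0.35/0.25 and a shared family — the multi-mapping
  artifact (near-equal shares, but unequal enough that "most abundant
  member" is well defined);
- two *differential* genera scaled 4-fold in group Y;
- one *rewiring* genus loading a shared log-normal factor with partner set
  S (4 genera) in X and with a disjoint set T (4 genera) in Y; the factor
  loading targets a within-module log-scale correlation of 0.9.

Defaults are 40 genera and 60 samples per group, so a full pipeline run
takes well under a second and the planted effects clear the default 0.4 /
0.005 thresholds with margin. The rewiring genus is itself one of the
differential genera: core taxa anchor Steps 4–5, so the planted rewiring is
only observable downstream if its carrier is selected as core — coupling the
two planted effects mirrors the method's own logic. The second differential
genus gets a stable companion so it has a network edge and survives
joint-isolate pruning.

What the generator does *not* emulate: 16S amplification or sequencing
error, chimeras, batch effects, overdispersion beyond the log-normal basis,
or realistic phylogenetic correlation structure. Passing the recovery tests
therefore shows the pipeline detects the planted signal classes under clean
compositional noise — not that it is robust to every artifact of real
surveys.

# Problem sizes and numerical choices

The test suite and the acceptance script use: 200 random weighted graph
pairs (≤ 30 nodes) for the scoring identity, 100 pairs for the 0/1
reduction, 100 random tie-free draws (n, m ≤ 6) against exhaustive
permutation enumeration, 20 replicates of 20 genera × 200 samples for the
null-sparsity and planted-correlation (ρ = 0.8, tolerance ± 0.15) checks,
and 50 seeded default fixtures for end-to-end recovery — sizes chosen so
the whole suite completes in well under a minute on one core while keeping
the Monte-Carlo rates stable.

Numerical details worth knowing: basis variances are clamped at 1e-10
before the square root; correlation estimates are clipped to [−1, 1];
adjacency symmetry is enforced to 1e-9 and restored by averaging
`(A + t(A))/2` at construction; representative and sorting ties break
lexicographically; group order in a ContractionMap follows the first
member's position in the effective-taxon list, so output is stable across
runs.

# Limitations

- Genus-level input with a single parent level; no multi-rank taxonomy.
- Exactly two groups; no longitudinal or multi-group designs.
- The contraction can in principle unify genuinely co-occurring sibling
  genera — the price of removing the multi-mapping artifact; use
  `skipContraction` when the distinction matters.
- SparCC's bootstrap p values are not computed; thresholding acts on raw
  coefficients.
- Scores are descriptive ranks, not significance statements; no null
  distribution for QNetDiff is provided.
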