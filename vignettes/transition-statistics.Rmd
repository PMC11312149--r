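---
title: "Chromatin-state transition statistics between differentiation stages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromatin-state transition statistics between differentiation stages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromtransit)
```

## The problem

When a cell population moves from one differentiation stage (condition A)
to the next (condition B), its regulatory genome is rewired: histone-mark
combinations ("chromatin states") change on a fixed 200-bp grid,
chromatin accessibility peaks appear and disappear, transcription factors
(TFs) gain or lose activity, and a new TF–TF regulatory circuit emerges.
`chromtransit` implements the downstream statistics that turn
already-processed inputs — per-bin chromatin-state calls, differential
accessibility statistics, motif enrichment Z-scores, footprint
enrichment p-values, expression tables and differential network edge
scores — into interpretable calls: which state transitions are enriched,
which are associated with gene deregulation or accessibility change,
which TFs are specifically active in the target stage, and which TF–TF
interactions survive a conservative evidence chain.

Upstream processing (alignment, peak calling, segmentation model
learning, footprint detection, network inference) is out of scope; its
outputs are this package's inputs.

## Transition enrichment

For tracks $A$ and $B$ on the same grid, the observed count
$O(s_1 \to s_2)$ is the number of bins in state $s_1$ in $A$ and $s_2$
in $B$ (identical-state pairs included). The null holds $A$ fixed and
uniformly permutes the $B$ calls genome-wide; the expected count $E$ is
the mean of $O$ over 1000 shuffles (`expected_counts(method =
"permutation")`). Because the shuffle preserves both state marginals,
its expectation has the closed form

$$E(s_1 \to s_2) = \frac{n_A(s_1)\, n_B(s_2)}{N},$$

which `method = "analytic"` returns and which the test suite uses as an
oracle for the permutation estimate. The enrichment score $ES = O/E$
controls for state coverage; the directional fold enrichment

$$FE(s_1 \to s_2) = \frac{ES(s_1 \to s_2)}{ES(s_2 \to s_1)}$$

controls for the intrinsic similarity of the two states. By
construction $FE(s_1 \to s_2)\,FE(s_2 \to s_1) = 1$ and the diagonal is
1. When the reverse score is 0 the fold enrichment is undefined and
reported as `NA` rather than 0 or infinity; an optional pseudocount on
$O$ is exposed for exploratory use but defaults to 0. For display,
cells with $FE > 1.5$ supported by at least 200 bins are colored and
transitions with fewer than 200 bins are masked grey
(`mask_for_display()`).

Which of the two vectors is shuffled is immaterial for the expectation;
we permute the target condition with the source fixed, genome-wide
rather than per chromosome, since the independence expectation is
identical and nothing in the procedure is chromosome-aware.

## Transition–expression and transition–accessibility association

Every grid bin is assigned its nearest *expressed* protein-coding gene
(mean TPM > 1 in at least one of the two conditions) with a TSS within
50 kb; distance is the interval-to-point gap, 0 on containment, with an
inclusive cutoff, and ties break on the lexicographically smallest gene
id so the assignment is deterministic. For each transition (diagonal
included) the unique up-, down- and non-deregulated genes nearest to
its bins form the $T$ counts, all other bins' genes the control $O$
counts. Three two-sided Fisher exact tests compare the groups —
up vs down, up vs rest, down vs rest — each family BH-adjusted across
all transitions, alongside three ratio statistics (relative excess of
up over down, relative up fraction, relative down fraction). A
transition is `up_enriched` when $RATIO_{UPDOWN} > 1$, $RATIO_{UP} >
1.2$, $P_{UPDOWN} < 0.05$ and $P_{UP} < 0.05$, and symmetrically
`down_enriched`; thresholds are applied with strict inequalities as
stated. The accessibility variant replaces genes by bins holding Gain
or Lose peak summits (peaks assigned to bins by summit; a bin holding
both takes Gain and is flagged, a case the source procedure does not
cover).

Three interpretation choices were genuinely open and are resolved as
follows. Gene counts are unique per group — the quantity described is a
number of *genes*, not of bins — with per-bin multiplicity available
via `tally_neighbors(id = NULL)` for sensitivity analysis. The
classification thresholds are applied to the BH-adjusted p-values,
since the adjustment is introduced immediately before the rule; a
switch (`use_adjusted = FALSE`) restores raw p-values. Sidedness is not
stated; the conventional two-sided test is used, with direction imposed
by the ratio conditions.

A degenerate corner worth knowing: $RATIO_{UPDOWN}$ divides by the
control group's relative up–down excess, which is near 0 with a random
sign when up and down annotations are exactly balanced in the controls.
The statistic presupposes a net direction in the background, which real
differentiation contrasts have; the synthetic generator therefore uses
a mildly asymmetric background for accessibility (Gain rate 0.02 vs
Lose rate 0.015 per bin) rather than a knife-edge balanced one.

## Integrated TF activity

Motif-level evidence is combined across three conditions. Footprint
enrichment adjusted p-values are transformed to $-\log_{10}p$ after
flooring zeros at $10^{-16}$, then averaged over each condition's DAR
sets (a motif untested in a set contributes $p = 1$, i.e. score 0,
keeping averages comparable); the default mapping of the six DAR sets
to conditions assigns each contrast's Lose sets to its A stage and Gain
sets to its B stage, and is configuration-driven because the assignment
is a reconstruction. Expression Z-scores standardize log2 mean TPM per
TF across the conditions using the population standard deviation — the
conditions *are* the population — and a constant row scores 0. A
(motif, TF) pair is called active iff: absolute motif Z-score ≥ 2 in
some condition; footprint adjusted p < 0.001 in some DAR set; TF TPM >
5 in some condition; the TF is differentially expressed in some
contrast; and the motif Z profile has Pearson r > 0.5 with both the
footprint scores and the expression Z-scores. Correlations over three
points are accepted as stated; a zero-variance profile has undefined
correlation and fails the filter. TPM is logged without pseudocount
because selected TFs have passed the expression filter; zero TPM in any
condition is rejected with a pointer to the `pseudocount` argument.

## TF network assembly

Candidate TF→TF edges from a differential regulatory network are kept
iff the differential score exceeds 0.7; both TFs have mean TPM > 5 in
the target stage; both satisfy at least one of three disjunctive
activity criteria (integrated activity call, footprint enrichment in a
Gain-peak class at p < 0.001, or top-30 influence rank); and a Gain
peak carrying a footprint of the source TF lies within 50 kb (strict)
of the target TSS. Edges whose closest mediating peak is under 25 kb
are flagged for display, so displayed edges are a subset of the
network. The four predicates commute — the kept set is independent of
filter order. Binding peaks of the profiled receptor are classified
Enriched (log2FC ≥ 1), Depleted (≤ −1) or Equal (inclusive outer
bounds as stated); input-subtracted counts are floored at 0 and get a
pseudocount of 1 before the ratio, a documented approximation that only
affects peaks with |log2FC| near 1. A TF is a direct target of the
receptor when it is the nearest protein-coding gene (no distance cap)
of a peak called in the target condition and is upregulated in the
relevant contrast; direct targets that are also upregulated in the
expanded contrast are labeled as such, remaining TFs split into
signal-responsive (upregulated) and non-responsive. Externally known
nodes can be forced in through configuration rather than code.

## Marker-panel similarity

Bulk samples are compared to reference single-cell clusters by the
Spearman correlation of log10-transformed expression over each
cluster's top TF marker panel, after ortholog mapping; unmapped markers
are dropped and counted, and clusters with fewer than three usable
markers return `NA`. The log uses a pseudocount of 1 to admit zeros —
irrelevant to the rank correlation (monotone) but kept for exported log
profiles. Ties receive average ranks. When reference profiles are
unavailable, `marker_concordance()` counts panel markers with query
TPM strictly above 5.

## The synthetic generator

The generator emulates the statistical structure the analysis assumes,
at a scale where everything runs in seconds: two 10-Mb chromosomes at
200 bp (100,000 bins), nine states, 2000 genes, per-bin i.i.d. state
pairs drawn from a configurable joint law. Defaults place ~78% of the
genome in the quiescent state with a few percent in each marked state,
and put half the mass on the diagonal (states persist), which keeps
both marginals at the chosen coverage and all off-diagonal fold
enrichments at 1 — a calibrated null. Planting a fold enrichment
multiplies a cell and renormalizes; because that shifts the pair's
marginals, the multiplier is solved (damped fixed point) so the
*realized* directional fold enrichment equals the requested factor
exactly, and an unattainable request (a planted cell too large for its
marginals) is an error rather than a silent shortfall.

Genes get TSSs uniform over the genome except for a planted minority
placed one-per-bin (without replacement) into distinct bins of a
designated transition; each gene's DE label is drawn from the law of
its own bin's transition. This geometry is deliberate: the association
statistic compares genes nearest to transition bins against genes
nearest to all other bins, and any planted gene is also the nearest
gene of surrounding control bins. Planting a large *fraction* of genes
therefore contaminates the control composition and destroys the very
association being planted, no matter how strong the per-gene odds; a
small planted minority in fully covered transition bins keeps the
transition group at the planted law and the controls at background.
The default planted conditions (~250–350 transition bins, ~250–300
planted genes, up probability 0.6 against a 0.1 background — an odds
ratio of about 13) follow from that analysis and are fixed.

Peaks are placed at most one per bin (so summits never collide), with
Gain/Lose probabilities per transition and a Common background; in
statistics mode each peak's (log2FC, FDR, replicate flags) are drawn so
the classification rule reproduces the intended class, giving a
round-trip check on the rule itself. TF-activity inputs plant coherent
TFs that pass all five filters and decoys that each violate exactly one
(low Z, footprint p above threshold, low TPM, no differential
expression, anti-correlated expression, anti-correlated footprints),
one negative control per filter. Network inputs lay TF genes 150 kb
apart with 100-kb chromosome-end margins — far enough that a mediating
peak (< 80 kb from its target) can never fall within 50 kb of a
neighboring TF — plant true edges that pass the whole chain (half with
mediating peaks under 25 kb) and false edges that each violate exactly
one predicate.

What the generator does *not* emulate: spatial autocorrelation of
chromatin states (bins are exchangeable, which is all the statistics
see; run-length structure only matters for IO, which the
segmentation-file round-trip covers), linkage between gene expression
and peak placement, sequence content, and replicate-level noise in the
upstream statistics. Passing tests therefore validate the statistics
and their implementation, not the upstream tools.

## Numerical choices and problem sizes

Fisher exact tests use the standard two-sided hypergeometric rule and
are validated against exhaustive same-margin enumeration (all tables
with N ≤ 12, plus randomized tables to N = 50, tolerance 1e-12); BH
adjustment is validated against the step-up closed form. All
coordinates are 0-based half-open; bin `b` covers `[200b, 200(b+1))`.
Rasterizing a segmentation resolves partially covered bins by majority
overlap with ties to the earlier file row; uncovered bins default to
quiescent. Tests and the acceptance script run the permutation null at
1000 shuffles on the full 100,000-bin genome, the association recovery
at 100 planted and 200 null seeds, TF-activity recovery at 20 seeds,
and network recovery at 5–10 seeds; the end-to-end pipeline on the
default genome completes in well under two minutes on one CPU and is
byte-identical across reruns with the same seed.

## Known limitations

Permutation mode recomputes the full joint tabulation per shuffle
(O(n_perm · N)); the analytic expectation is exact and instant, so
permutation mode exists mainly to demonstrate the null and to expose
the permutation distribution. The nearest-gene assignment ignores
strand, as the procedure defines the TSS as a point. The Fisher tests
treat bins and genes as exchangeable units; spatially correlated state
calls in real data make the effective sample size smaller than the bin
count, so p-values on real genomes are anti-conservative in the same
way as in the source procedure — the ratio thresholds, not the
p-values alone, carry the classification. The RATIO_UPDOWN statistic
is unstable when the control group is exactly balanced (see above).
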