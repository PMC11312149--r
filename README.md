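# chromtransit

Statistics for comparing the regulatory genome of two differentiation
stages. Given per-bin chromatin-state calls for two conditions on a
fixed 200-bp grid, differential chromatin-accessibility peaks, gene
expression tables, motif/footprint enrichment matrices and a
differential regulatory-network edge table, `chromtransit` computes:

- **Transition enrichment** — observed vs permutation-expected counts
  for every ordered chromatin-state pair. With `n_A`, `n_B` the state
  marginals over `N` bins, the shuffled expectation is
  `E(s1→s2) = n_A(s1)·n_B(s2)/N`; the enrichment score is `ES = O/E`
  and the directional fold enrichment
  `FE(s1→s2) = ES(s1→s2)/ES(s2→s1)` controls for the intrinsic
  similarity of the two states.
- **Transition association** — for each transition, Fisher exact tests
  comparing up/down/unchanged genes nearest to the transition's bins
  (`UP_T, DOWN_T, NO_T`) against all other bins (`UP_O, DOWN_O, NO_O`),
  BH-adjusted per test family, plus the ratio statistics
  `RATIO_UPDOWN`, `RATIO_UP`, `RATIO_DOWN` and the threshold
  classification (`RATIO_UP > 1.2`, `P < 0.05`, ...). A peak-mode
  variant replaces genes with bins holding Gain/Lose peak summits.
- **Integrated TF activity** — joins motif enrichment Z-scores,
  footprint (FP) enrichment scores (condition averages of
  `−log10(adjusted p)`, zeros floored at 1e-16) and expression
  Z-scores; a motif is called active iff `|Z| ≥ 2` somewhere, FP
  `p < 0.001` somewhere, TF TPM > 5 somewhere, the TF is
  differentially expressed, and the Z profile correlates (Pearson
  r > 0.5) with both FP scores and expression.
- **TF network assembly** — keeps TF→TF edges with differential score
  > 0.7, both TFs expressed (TPM > 5) and active by at least one of
  three criteria, and a mediating Gain peak carrying a source-TF
  footprint within 50 kb of the target TSS (< 25 kb flags the edge for
  display); classifies receptor binding peaks
  (Enriched/Equal/Depleted) and stratifies network TFs by direct
  targeting and signal responsiveness.
- **Marker similarity** — Spearman correlation of bulk samples against
  reference cluster profiles over top-TF marker panels, and TPM > 5
  marker-concordance counts.

A first-class synthetic-data generator (`simulation_config()`,
`simulate_*()`) plants known signal in every input — joint transition
structure, transition-associated gene deregulation, peak classes,
coherent vs decoy TF profiles, a true edge set — so the whole pipeline
is validated against ground truth without any sequencing data.

## Worked example

Plant a modest enrichment of the Polycomb-repressed → active-enhancer
transition, with upregulated genes spatially associated to it, then
recover both:

```r
library(chromtransit)

jw <- transition_weights(
  planted = data.frame(from = "ReprPC", to = "EnhA", fe = 3.125))
cfg <- simulation_config(
  joint_weights = jw,
  tss_law = list(transition = "ReprPC->EnhA", frac = 0.15),
  de_association = list(default = c(up = 0.1, down = 0.1),
                        "ReprPC->EnhA" = c(up = 0.6, down = 0.05)))

tracks <- simulate_state_tracks(cfg, seed = 7)
counts <- count_transitions(tracks$track_a, tracks$track_b)
E      <- expected_counts(tracks$track_a, tracks$track_b, "analytic")
enr    <- fold_enrichment(counts, E)
round(enr$FE["ReprPC", "EnhA"], 2)
#> [1] 2.6

genes <- simulate_genes(cfg, tracks, seed = 8)
assoc <- associate_genes(tracks$track_a, tracks$track_b, genes,
                         contrast = "DEvsPE")
subset(assoc, s_from == "ReprPC" & s_to == "EnhA",
       select = c(UP_T, DOWN_T, NO_T, q_updown, q_up,
                  ratio_updown, ratio_up, label))
#>    UP_T DOWN_T NO_T     q_updown         q_up ratio_updown ratio_up       label
#> 37  145     19  173 1.545357e-06 2.420987e-19     4.388578 2.435346 up_enriched
```

The fold enrichment for the planted pair is well above 1 (the planted
law's own value is 3.125; 2.6 reflects sampling noise in the ~100
reverse-direction bins), and the association stage flags exactly that
transition as enriched in nearby upregulated genes: 145 of the 337
genes nearest to its bins are upregulated, a 2.4-fold excess over the
control bins with BH-adjusted p-values far below 0.05.

The full pipeline — simulation, transition enrichment with the
1000-shuffle null, both association modes, TF activity and network
assembly, all written as TSV/GraphML plus a JSON run manifest — runs
from one call or from the command line:

```r
run_pipeline(pipeline_config(outdir = "out", seed = 1))
```

```sh
Rscript inst/scripts/chromtransit.R all --seed 1 --outdir out
```

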