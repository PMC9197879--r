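# mlimorph

Morphometric cell typing and morphological pseudotime for cerebellar
molecular layer interneurons (MLIs).

MLIs — the basket cells (BCs) and stellate cells (SCs) of the cerebellar
cortex — arise from a common progenitor pool, and whether they form two
discrete types or one continuously varying population has been debated
since Cajal. `mlimorph` implements a quantitative-morphology pipeline for
this question, end to end and offline-testable:

* **Reconstruction IO and morphometrics.** SWC reading/writing, a
  per-section molecular-layer coordinate frame, and the mature (27) and
  developmental (28) morphometric feature panels: cable lengths, Sholl
  intersections at 10/50/100/150/200 µm, branch levels, straightness,
  filopodia (terminal dendritic branches < 1.5 µm), laminar spans, upward/
  downward axon collaterals under the >30° inclusion rule, the weighted
  basket score (full basket 1, basket-like 0.75, partial 0.5), ellipsoid
  soma volumes, and relative laminar position (soma height / ML thickness).
* **Clustering with stability analysis.** Zero-mean standardization, Ward
  hierarchical clustering into BC/SC clades, dendrogram leaf ranks, Newick
  export, subsample cross-validation (resample n cells, recluster, score
  clade recovery against reference labels), recursive feature elimination
  with adjusted-Rand agreement, 2-D embeddings, and a dip-statistic
  bimodality screen.
* **Morphological pseudotime.** An adaptive-kernel kNN affinity graph,
  diffusion-map components, and accumulated diffusion pseudotime (DPT)
  from a robustly chosen immature start cell, with Louvain community
  states (k = 20), expert-stage concordance, and bootstrap feature trends
  along the pseudo-timeline.
* **Fate co-sorting statistic.** Per 0.2-wide pseudotime bin and per
  birthdate cohort (P0-induced BC-fated vs P4–7-induced SC-fated), the
  mean fraction of each cell's 5 nearest embedding neighbours sharing its
  fate, compared against the bin's fate-frequency null
  (`count(fate)/count(bin)`) with paired bootstrap confidence intervals,
  per-bin one-sided t-tests, and an optional calibrated within-bin
  permutation test.
* **Synthetic data with ground truth.** Seeded generators for mature
  two-type populations (with the continuous short-to-long-axon SC
  gradient), developmental two-fate trajectories (latent maturation `s`,
  configurable divergence point, hump-shaped SC axon span, a rare
  early-born SC lineage), and SWC trees whose every feature value is known
  analytically at construction time.

## The statistics at the core

For cell *i* with fate *f(i)* and 5 nearest neighbours *N(i)* in the
embedding, the co-sorting fraction is
*p̂ᵢ = |{j ∈ N(i) : f(j) = f(i)}| / 5*. Within pseudotime bin *b*, the
observed mean of *p̂ᵢ* over fate-*f* cells is tested against the null
*n_{f,b}/n_b* (the fate's frequency in the bin, i.e. neighbour identities
carry no information beyond bin composition) with a one-sided t-test, and
interval-estimated by resampling whole bins and recomputing both the mean
and the null on each resample. Pseudotime itself is the accumulated
diffusion distance Σₗ (λₗ/(1−λₗ))·(ψₗ(i) − ψₗ(root))² on the adaptive kNN
graph, min–max normalized to [0, 1].

## Worked example

```r
library(mlimorph)

## mature population: two clades and their subsample stability
sim <- simulate_mature(seed = 1)            # 19 BC-like + 60 SC-like cells
cl  <- hcluster(standardize(sim$table))
cl
#> Hierarchical clustering (ward/euclidean): 79 cells in 2 clades
#> clade
#>  A  B
#> 63 16
subsample_cv(sim$table, cl$labels, sizes = c(10, 20, 40), trials = 20,
             seed = 2)
#> Subsample cross-validation (20 trials per size, seed 2)
#>    size mean_accuracy    sem
#>      10        0.9100 0.0191
#>      20        0.9000 0.0150
#>      40        0.9312 0.0112

## development: pseudotime and fate co-sorting
dev  <- simulate_development(seed = 1)      # 423 + 309 cells, early divergence
pt   <- morpho_pseudotime(dev$table, seed = 1)
fate <- setNames(dev$table$metadata$fate_label, dev$table$metadata$cell_id)
cosort(pt$pseudotime, pt$embedding, fate, reps = 500, seed = 1)
#> Nearest-neighbour fate co-sorting (k = 5)
#>      fate bin   n mean_fraction ci_lo ci_hi null_fraction     t  p_value
#>  BC_fated   0  90         0.727 0.643 0.820         0.621  4.31 2.08e-05
#>  ...
#>  SC_fated   0  55         0.564 0.456 0.680         0.379  3.99 9.91e-05
#>  ...
```

Reading the output: the two-clade cut recovers the generator's BC/SC split
(16 vs 19 planted basket-like cells; reclustering only 20 random cells
already reproduces the division at 90% mean accuracy), and in the earliest
fifth of the pseudo-timeline each cohort's neighbours are already enriched
for its own fate well beyond the bin's fate-frequency null (72.7% vs 62.1%
for the early-born cohort, 56.4% vs 37.9% for the late-born cohort) — the
signature of fate divergence at the very start of axonogenesis rather than
after cells settle at their final laminar positions.

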