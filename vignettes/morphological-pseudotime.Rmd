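---
title: "Morphometric typing and morphological pseudotime: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometric typing and morphological pseudotime: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlimorph)
```

This vignette is the package's account of its science: the measurement
conventions behind each morphometric feature, the clustering and
pseudotime models and their assumptions, what the synthetic-data
generators emulate (and what they do not), and the numerical and design
choices made where conventions were genuinely open. It states no numbers
that the test suite and `scripts/acceptance.R` do not themselves compute.

## 1. The biological question and the pipeline shape

Cerebellar molecular layer interneurons (MLIs) comprise basket cells
(BCs), which innervate Purkinje cell somata through characteristic basket
terminals from the lower molecular layer (ML), and stellate cells (SCs),
which innervate Purkinje dendrites from the upper ML. Because most MLIs
show intermediate morphologies, it has long been disputed whether the
BC/SC division is discrete or a continuum indexed by laminar depth. The
pipeline addresses this in two movements:

1. **Mature typing.** Quantify tens of morphometric features per
   reconstructed neuron, standardize, cluster (Ward), and probe the
   robustness of the resulting two-clade division by reclustering random
   subsamples and by recursive feature elimination.
2. **Developmental ordering.** For large sets of developmental snapshot
   reconstructions annotated with a birthdate cohort (tamoxifen induction
   at P0 marks early-born, predominantly BC-fated cells; P4–7 marks
   late-born, SC-fated cells), infer a maturation pseudo-timeline from
   morphometry alone, then ask *when* the cohorts become morphologically
   distinguishable: the nearest-neighbour co-sorting statistic per
   pseudotime bin, against a per-bin fate-frequency null.

## 2. Measurement conventions (morphometrics)

All features operate on a validated SWC tree with a per-section layer
frame (`layer_geometry`): `normal` points from the Purkinje cell layer
(PCL) top to the ML top, `tangential` runs along the PCL sagittally, `z`
along the parallel fibres. Conventions that required a decision:

* **Edges belong to their child node's compartment**; a branch segment is
  a maximal unbranched chain of compartment edges, and branch level counts
  the branch points between the compartment attachment and the segment
  (an unbranched process is level 0; where several primary dendrites leave
  one soma node, that node is itself a branch point and primaries start at
  level 1).
* **Sholl intersections** count edges whose endpoint distances from the
  soma centroid straddle the radius, so a process that exits and re-enters
  a sphere is counted at each crossing. Default radii 10/50/100/150/200 µm.
* **Straightness** is chord over arc per segment, aggregated
  length-weighted (equivalently total chord / total arc); an unweighted
  mean is available since the originating software's aggregation is not
  documented.
* **Filopodia** are terminal dendritic segments strictly shorter than
  1.5 µm; density divides by total dendritic cable.
* **Collaterals**: the main axon is the geodesically longest root-to-tip
  axonal path (the long horizontal shaft of a basket cell under this
  rule); side branches whose initial direction deviates from the local
  shaft direction by more than 30° are classed upward/downward by the sign
  of the normal component. Directions are secants over the first
  min(5 µm, branch length) of arc, which makes the angle robust to node
  jitter. Both thresholds are arguments.
* **Weighted basket score** = 1·full + 0.75·basket-like + 0.5·partial
  soma-targeting terminals; these counts are image annotations, not
  derivable from an SWC, and enter through `annotation_record`.
* **Ellipsoid soma volume** defaults to V = 4/3·π·dx·dy·dz over the three
  measured diameters, the formula under which the developmental soma
  volumes this package targets were produced; the geometrically standard
  π/6·dx·dy·dz is available as `formula = "geometric"`. The two differ by
  a constant factor 8 and are interchangeable after standardization.
* **Soma position** is the unweighted centroid of soma nodes, accepting
  both single-point and contour-style somata; relative laminar position is
  soma height over ML thickness.
* Feature schemas (`mature_27`, `developmental_28`, `clustering_19`) are
  editable objects. Their default memberships are field-plausible but
  provisional — published panels vary, and the clustering subset exists to
  compile the four basket-related measurements into the single weighted
  score so soma-targeting information is not over-weighted.

## 3. Clustering and stability

Standardization is zero-mean with population (1/n) SD, which makes
`standardize` exactly idempotent; a sample-SD flag exists. Ward linkage on
Euclidean distances is the canonical pairing (`hclust` method `ward.D2`);
determinism follows from the input order and `hclust`'s merge rule.

`subsample_cv` standardizes **once** on the full table and reclusters
random row subsets. Re-standardizing within a subsample was rejected: in a
five-cell subsample containing one basket cell, per-feature
standardization caps the outlier's z-score near √(n−1) regardless of the
true separation, so even arbitrarily well-separated classes cannot be
recovered perfectly — an artifact of the resampling design, not a property
of the data. Clades are identified with the reference label of the
majority of their members; ties resolve to the label minimizing
misclassification, then alphabetically. Note one bias worth knowing:
because each clade is labelled by its own majority, accuracy at small
subsample sizes sits slightly above the majority-class prior even for
completely uninformative features; chance-level checks should use sizes of
roughly 40 and above, where the bias is below 0.01.

Feature-ablation agreement is the adjusted Rand index against the baseline
labels, with 0.9 as the conventional "division preserved" threshold. The
optional `dip_screen` implements a dip-style unimodality statistic
(greatest-convex-minorant / least-concave-majorant envelope deviation over
a grid of candidate modes) with a uniform-resampling null; it flags
features that are bimodal on their own, which none should be if the clade
division is a joint property of the panel.

## 4. Diffusion pseudotime

The trajectory model assumes a dominant, globally linear maturation axis
in standardized feature space, sampled with per-feature noise. The
machinery is the standard diffusion-map/DPT stack:

* adaptive Gaussian kernel on k nearest neighbours (bandwidth = distance
  to the k-th neighbour, affinities symmetrized by union/max, self-loops
  excluded);
* spectral decomposition of the row-normalized transition operator via
  its symmetric conjugate; components are the non-trivial right
  eigenvectors, eigenvalue-scaled;
* pseudotime = accumulated multi-scale diffusion distance from the start
  cell, i.e. Euclidean distance after reweighting component ℓ by
  λℓ/(1−λℓ), min–max normalized to [0, 1]. The accumulated weighting
  (the sum of the diffusion distances over all diffusion times) is what
  makes the estimate robust: it amplifies the slow trajectory axes
  relative to fast noise modes, and on the synthetic study conditions it
  raises latent-maturation recovery from Spearman ≈ 0.84 (single-scale
  eigenvalue weighting) to ≈ 0.95–0.98.

Defaults: 5 components; trajectory graph k = 10; community graph k = 20
with Louvain modularity communities. Two defaults deserve justification.
First, k = 10 rather than the k = 3 recorded for PHATE-style analyses:
k = 3 there parameterizes a dense decaying kernel, whereas a literal 3-NN
graph at several hundred cells fragments easily and loses a few percent of
recovery in a sizeable minority of simulations; k = 3 remains available.
Second, the start cell. Expert staging marks the most immature cells, but
anchoring the trajectory at the single stage-1 cell with the smallest
axon is fragile — one noisy measurement can hand the root to a cell well
past the fate divergence, which misaligns the two fate branches (each
branch is internally well ordered, but their pseudotime scales shift
against each other). The default therefore scores stage-1 cells by a
composite axonal-size score (mean standardized value over axon length,
tangential span, ML height covered, and soma volume, as available), takes
the eight most immature candidates, and anchors at their medoid in
diffusion-component space. `start_cell` overrides everything.

Cells outside the largest graph component are dropped with a warning.
Degenerate inputs: duplicate rows get capped affinity on their
zero-distance edge; a non-finite eigen-solve and an all-coincident
component space are errors, not silent results.

Feature trends along pseudotime are binned means with percentile bootstrap
CIs per fate group — deliberately simple; a smoothing-imputation step used
in some reference workflows is not reproduced, because binned bootstrap
means make the uncertainty explicit and detect the non-monotone patterns
of interest (the SC axonal span's expansion-then-retraction) without extra
machinery.

## 5. The co-sorting statistic and its inference

For each cell, the fraction of its k = 5 nearest embedding neighbours
sharing its fate label; per 0.2-wide pseudotime bin (half-open, last bin
closed) and per fate, the mean fraction is compared to the bin's
fate-frequency null. Two inference choices required care:

* **Interval estimation.** Resampling cells within a (fate, bin) group and
  holding the null fixed produces intervals that cover a true null in only
  ~80% of no-divergence replicates: per-cell fractions are positively
  correlated (nearby cells share neighbours), and the null itself
  co-fluctuates with bin composition. The package instead resamples the
  whole bin and recomputes both the mean fraction and the null on each
  resample; the reported interval is the observed null plus the percentile
  interval of the resampled differences, clamped to [0, 1]. Measured
  coverage under the no-divergence generator is ~98–99% (the acceptance
  script recomputes this).
* **Testing.** The default per-bin test is the conventional one-sample,
  one-sided t-test of per-cell fractions against the null. Because the
  fractions are not independent, this test rejects a true null at roughly
  twice the nominal rate (measured ~0.10 at α = 0.05). It is retained as
  the field-standard default, and a calibrated alternative is provided:
  `test = "permutation"` shuffles fate labels within bins (preserving
  every bin's composition and the neighbour graph) and recomputes the
  statistic, which is exact under within-bin exchangeability; its measured
  rejection rate at α = 0.05 is ~0.04–0.06. No multiple-testing
  correction is applied by default (per-bin p-values are reported
  uncorrected, as is conventional for this display); Holm adjustment is a
  flag.

For the neighbour space, a top-5 principal-component embedding of the
standardized table (`pc_embedding`) is recommended: the reference
protocols also run PCA before manifold learning, and with tens of
partially redundant features the leading components retain the maturation
and fate axes while shedding per-feature noise. The trajectory fit's own
2-D diffusion embedding works but is noisier for this purpose, since on a
long trajectory the top components are dominated by arclength harmonics.

## 6. What the generators emulate — and what they do not

`simulate_mature` draws class-conditional Gaussians with diagonal
covariance: 19 basket-like and 60 stellate-like cells by default, the
class mean difference confined to a six-feature informative (axonal)
group at two noise SDs per feature, and a continuous uniform gradient on
the axon-span features of SC cells only — the short-to-long-axon stellate
continuum. Zero separation and zero gradient give the null population for
chance-level checks.

`simulate_development` draws a latent maturation variable `s` per cell
from truncated-Gaussian windows around 8 evenly spaced snapshot centres
(jitter SD 0.06), emulating the mixture of developmental stages present in
tissue at any collection age; 423 early-born and 309 late-born cells by
default, with 5% of the early-born cohort following a rare short-range
SC trajectory (distinct lineage, same birthdate cohort — the configuration
under which community detection isolates a small rare-lineage community).
Most features grow linearly in `s` with order-1 slopes and Gaussian noise
SD 0.2. Fate divergence starts at `s_div` (default 0.1) and saturates on
a commitment timescale of 0.12 — about one snapshot window — in mirrored
directions on a set of weakly growing features (descending vs ascending
collaterals, PCL-reaching branches, laminar position), i.e. transversally
to the growth axis. The SC axonal span additionally follows a
rising-then-falling deviation with an interior peak and net late decline.
With `s_div = 1` the fates never diverge: the mean trajectories are
exactly identical, which is the null scenario for calibration.

The transversal, saturating design is deliberate and sits at a measured
corner of the design space: divergence must be fast and large enough that
the cohorts are distinguishable already in the earliest fifth of the
timeline (the regime the real data occupies, where cohorts co-sort from
the earliest observed stage), yet remain subordinate to the shared growth
axis — when fate deviations are piled onto the dominant growth features
or made near-instantaneous, the leading diffusion component becomes the
fate split and pseudotime recovery collapses. Both requirements are
checked by the test suite at the defaults.

What the generators do **not** emulate: correlated feature noise,
measurement censoring (cut arbors), batch effects across injection
cohorts, non-Gaussian heavy tails, and any real morphological covariance
structure. Passing tests therefore demonstrate that the pipeline's
machinery is correct and calibrated under its stated assumptions — not
that those assumptions hold for any particular real dataset.

`simulate_swc` builds reconstructions whose features are known exactly at
construction: straight radial dendrites with terminal filopodia and longer
side branches, a straight tangential axon shaft with collaterals at
configured angles above and below the 30° threshold, a point soma at a
known laminar height, and annotated soma diameters and basket-terminal
counts. All segments are straight polylines, so lengths, spans, Sholl
crossings, branch levels, straightness and collateral classes follow from
the construction arithmetic; the extractor is required to match to 1e-6
relative tolerance (observed: machine precision).

## 7. Problem sizes and reproducibility

Every stochastic function takes a seed and is a pure function of it. The
standard experiment sizes, chosen to mirror the study conditions while
keeping a laptop-scale footprint: 79 cells for the mature analyses; 700
cells (400 + 300) for the pseudotime recovery sweep at noise SD 0.2 over
10 seeds; 500 replicates of 250 cells for co-sorting calibration; 5
replicates at the full 732-cell condition for the early-divergence check.
`scripts/acceptance.R` re-runs all of these from a single command-line
seed and writes the measured quantities as JSON.

## 8. Known limitations

* The diffusion trajectory assumes one dominant, roughly linear
  maturation axis. Strongly branching topologies (beyond a transversal
  two-fate split) and large-scale regressive phases that fold the
  manifold will degrade the ordering; the per-fate orderings typically
  survive such folds better than their common alignment.
* The default t-test's mild anticonservatism is inherited from treating
  correlated per-cell fractions as independent; use the permutation test
  where type-I control matters.
* Schema memberships are provisional defaults, and features that require
  image annotations (basket terminal categories, rendered soma volume)
  pass through `annotation_record` rather than being computed.
* `dip_screen` uses a grid-restricted envelope construction that upper
  bounds the exact dip; it is a screen, not a formal test.
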