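---
title: "Methods: spatial niches, colocalization and crosstalk in spatialTME"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial niches, colocalization and crosstalk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models behind spatialTME, the
parameters that matter, the design choices made where the design was
genuinely open, and what the synthetic cohorts do and do not establish
about real data.

## The data model

All analyses operate on a per-cell table (coordinates in μm, an
FOV → tissue core → patient hierarchy, a region label — T tumor core,
B invasive boundary, N adjacent normal — and a cell type) plus a sparse
gene × cell count matrix. FOVs are treated as independent spatial units:
imaging tiles are registered independently, so no neighbor relation ever
crosses an FOV boundary and no global stage coordinates are
reconstructed.

Counts are quality-filtered by total transcripts per cell
(`min_transcripts = 20`, the usual convention for imaging platforms,
where low totals flag failed segmentation) and normalized by per-cell
scaling to a 500-count total followed by `log1p`. A Pearson-residual
style variance stabilization would also work; the downstream tests are
rank-based (Wilcoxon) and correlation-based, which need only a monotone,
library-size-free view, so the simpler transform is preferred and is
configurable (`target_total`, `pseudo`).

## Colocalization quotient

For types A and B within one FOV of $N$ cells,

$$\mathrm{CLQ}_{A\to B} =
  \frac{\tfrac{1}{N_A}\sum_{i\in A} n_{i,B}/k_i}{N'_B/(N-1)},$$

with $n_{i,B}$ the number of B cells among the $k_i$ nearest neighbors
of A-cell $i$ and $N'_B = N_B - 1$ when $A = B$. The index cell is never
its own neighbor; the self-pair denominator correction is the standard
CLQ convention. A per-cell "local CLQ" divides each cell's neighbor
fraction by the same expectation; local values average exactly to the
FOV value. Values pool across FOVs as a mean weighted by the number of A
cells, equivalently the mean of all local CLQs — per-FOV densities are
the primary view, and no pooling rule dominates in the literature, so
the cell-weighted mean was chosen for its local-value interpretation.

Neighbor search is exact brute force per FOV (compiled), with distance
ties broken by cell id for reproducibility; at FOV sizes of a few
thousand cells this is faster and simpler than tree structures. The
default $k = 20$ for colocalization is deliberately smaller than the
niche $k = 50$: CLQ estimates a local fraction, and a tighter
neighborhood keeps it local; both are exposed as parameters.

Significance uses within-FOV label permutation (coordinates fixed),
two-sided on $|\mathrm{CLQ}-1|$, with the add-one estimator
$p = (1 + \#\{|CLQ^\ast - 1| \ge |CLQ - 1|\})/(n_{perm}+1)$, which is
never 0 and is uniform under exchangeability.

## Niches from neighborhood composition

Each cell is encoded by the type composition of its 50 nearest
neighbors (index cell excluded; the fraction uses the number of
neighbors actually available, so rows always sum to 1, and cells in
FOVs smaller than $k+1$ are kept with truncated, flagged
neighborhoods rather than dropped). Composition vectors are clustered
with k-means, Euclidean, best of 10 restarts, labels renumbered by
decreasing cluster size; given a seed this is fully deterministic.
k-means is the canonical clusterer for composition vectors — the
vectors live on a simplex of dimension (number of types − 1), distances
are meaningful, and determinism matters for pipelines. The default
K = 9 matches the package's reference cohort; `select_k` provides an
inertia elbow plus mean silhouette (computed on a 2000-cell subsample,
since the full distance matrix is quadratic) and recommends the
silhouette maximum.

Niche structure is summarized by log2 observed/expected enrichment
against cell types or regions, with both fractions floored at a
pseudo-fraction $1/(n+1)$ so empty combinations stay finite, and by
per-patient/region/FOV niche abundance (rows sum to 1), the covariate
used for survival.

Whether the index cell's own type belongs in its composition vector is
genuinely open; it is excluded here so that the vector describes the
cell's surroundings, not itself — including it mildly inflates
self-type coherence and changes little else.

## Proximity conditioning and differential expression

Two proximity predicates are provided, because both appear in practice
and they answer slightly different questions: *knn* (a target cell among
the first $t$ neighbors — adaptive to local density) and *radius* (a
target within $t$ μm — fixed physical scale; 80 μm is the conventional
diffusible range, ~30 μm a contact range). Both are evaluated within
FOV. The radius predicate is geometrically symmetric, and the generator
writes its coupling truth with exactly the same predicate, so analysis
flags and planted flags are interchangeable.

Differential expression between proximal and distal cells (and between
high/low-infiltration FOVs) uses a vectorized two-sided Wilcoxon
rank-sum with tie correction and continuity correction, numerically
identical to `wilcox.test(exact = FALSE)`, followed by
Benjamini–Hochberg across tested genes. Log2 fold changes are ratios of
group means with a 1e-9 pseudo. Groups below 20 cells are flagged
rather than refused.

## Range-gated ligand–receptor scoring

Within each FOV, eligible receivers have at least one sender within the
interaction range, and eligible senders reach at least one eligible
receiver. With $\bar L$, $\bar R$ the 10%-trimmed mean ligand/receptor
expression over eligible cells, the score is the Hill/mass-action form

$$s = \frac{\bar L \bar R}{K_h + \bar L \bar R} \in [0, 1),$$

zero iff $\bar L\bar R = 0$ and $1/2$ at half-saturation
$\bar L\bar R = K_h$ (default 0.5). This is a deliberate simplification
of pathway-level communication frameworks down to their mass-action
core, plus the spatial gating; trimming keeps single bright cells from
dominating a FOV. FOVs without an eligible pair score null and are
excluded from pooling (the pooled score uses all eligible cells across
FOVs). The permutation test shuffles type labels within FOVs and is
one-sided (large scores).

## Outcomes

Immune infiltration per FOV is the fraction of cells in a configurable
immune set (default T/NK, B/Plasma, Myeloid — "immune" is not a fixed
vocabulary, so the set is explicit); FOVs split at the median with ties
to "low". Survival uses the Kaplan–Meier product-limit estimator and
the two-group log-rank test via the survival package; covariates
(niche abundance, expression) are dichotomized at the median, ties to
"low", matching the high/low curve convention. No proportional-hazards
regression or covariate adjustment is attempted — the package follows
the univariable KM/log-rank design.

## The synthetic cohort generator

The generator exists so that every stage can be tested against known
truth. Its defaults define the package's reference conditions, chosen
once to mirror an HCC imaging cohort:

* 510 μm square FOVs (the CosMx tile scale); 6 patients × (2 T + 1 B +
  1 N) FOVs; ~480–580 cells per FOV, matching large-cohort averages of
  roughly 500 cells/FOV.
* 9 cell types: the 8 usual liver-tumor lineages with the CAF
  compartment split into mCAF/iCAF and endothelium represented by
  capillaries/LSECs.
* Nine planted niches (Matérn-style: Poisson-count uniform parents,
  Gaussian offspring, sd 20 μm, ~100 cells per cluster) with mixtures
  and region restrictions mirroring the recurrent HCC neighborhood
  states (e.g. a boundary-restricted T/DC niche, a normal-restricted
  iCAF-immune niche, an outcome-linked mCAF–cholangiocyte niche). The
  geometry is deliberately tight relative to the 50-neighbor window:
  a 50-NN disc must usually stay inside one cluster for planted labels
  to be recoverable at all; with looser clusters the ground truth
  itself becomes ambiguous at cluster borders.
* Region-shifted composition: mCAF share higher in T/B, iCAF share
  higher in N, both via niche placement and background mixtures.
* Negative-binomial counts (mean/size parameterization, size 2 —
  overdispersed but stable at small means), six markers per lineage,
  type mean vectors rescaled to an 800-transcript expected total (the
  platform's reported per-cell medians are ~800). 5% of cells are
  planted as low-count QC failures (expected total 5).
* The coupling: capillaries exclusively express the ligand DLL4; mCAF
  receivers within 30 μm of a capillary double the mean of a 30-gene
  NOTCH/ECM receptor program (planted log2FC = 1). The program is a
  small share (~1%) of receiver totals: the panel carries 200 neutral
  filler genes precisely so that per-cell normalization of a planted
  up-regulation does not induce detectable spurious down-shifts in
  unrelated genes — with a 300-gene panel and a 30-gene program at
  higher baseline, the compositional artifact alone would dominate the
  false-discovery count at n = 500 cells per group, as it would in any
  real panel where a regulated program is a large count share.
* Survival: exponential event times with hazard
  $h_0\exp(\beta \cdot \text{abundance})$ ($h_0 = 0.02$/month,
  $\beta = 3$ on the outcome niche's per-patient abundance fraction),
  exponential random censoring calibrated to ~20% at baseline, and
  administrative censoring at 120 months. Power checks use binary
  abundance at $\beta = \log 2.5$ with censoring off — the cleanest
  reading of a planted hazard ratio.

Determinism is part of the contract: identical config + seed reproduce
the dataset byte for byte, and all randomness in `generate_cohort`
flows from one seed.

### What the synthetic cohorts do not show

The generator emulates the statistical structure the analyses assume —
not real tissue. It has no segmentation error or transcript spillover
between adjacent cells, no spatial autocorrelation beyond the planted
clusters, type-homogeneous expression within a lineage, and independent
NB noise per gene. Passing tests therefore demonstrate correctness and
calibration of the estimators under their own model, and recoverability
of planted structure; they do not validate biological conclusions on
real cohorts, where mis-segmentation alone can fabricate proximity
effects.

## Numerical choices and degenerate inputs

* kNN ties: broken by (distance, cell id); the generator additionally
  jitters coincident coordinates by 1e-6 μm (inward, so cells stay in
  the FOV).
* Single-cell FOVs are excluded from graphs and flagged; empty planted
  FOVs are an error naming the FOV.
* CLQ is null (not 0) when a FOV lacks A cells or has no eligible B;
  null FOVs are counted and excluded from pooling.
* Wilcoxon degenerates (all values tied) return p = 1.
* Zero-variance vectors yield null correlations with an explanatory
  reason rather than an error; constant anchors/values are errors where
  a cutpoint or screen would be meaningless.
* Pseudobulk requires 5 cells of the type per FOV (below: null row,
  reported); DE q-values are flagged when a group has fewer than 20
  cells.
* Per-stage pipeline seeds derive from the global seed and the stage
  name, so adding a stage never shifts another stage's randomness.

## Problem sizes used in the test suite

The suite validates calibration at moderate sizes chosen to make
sampling error, not compute, the limiting factor: 200 CSR FOVs of 2000
cells for CLQ calibration (with 99-permutation p-values per FOV),
50 random instances against the brute-force CLQ oracle, the ~13k-cell
default cohort for niche recovery (ARI ≥ 0.8), five replicates of the
500-vs-500 planted coupling for DE sensitivity/FDR plus 50 pure-null
replicates, 100 replicates of the 60-FOV pseudobulk coupling, and 100
simulated 60-patient cohorts for log-rank power. Empirical FDR is
reported across replicates because a single run's false-discovery
proportion is an integer ratio with large variance at 30 true
positives.

## Known limitations

* CLQ pooling and the LR score's trimmed means are sensible defaults,
  not canon; both are parameterized.
* The LR scorer is a single-pair statistic: no pathway aggregation, no
  curated ligand–receptor database, no downstream-target modeling.
* k-means niches assume roughly isotropic composition clusters; graph
  clustering (Leiden) on a composition kNN graph is a reasonable
  alternative not implemented here.
* Survival is univariable by design; hazard ratios are planted and
  tested via log-rank power, not estimated by regression.
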