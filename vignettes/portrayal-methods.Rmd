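---
title: "SOM portrayal of expression cohorts: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SOM portrayal of expression cohorts: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somstrata)
```

somstrata turns a bulk expression cohort (genes x samples) into a
self-organizing-map (SOM) *metagene landscape* and carries the analysis
through to molecular subtypes: per-sample portraits, over-expression spot
modules, correlation-silhouette class discovery, gene-set Z-scores,
per-metagene ROC/AUC marker maps, immune-cell deconvolution and a minimal
pathway signal-flow engine.  This vignette explains the underlying models,
the tunable parameters, and the design choices made where the method
leaves room — together with what the synthetic cohort generator does and
does not emulate.

## Preprocessing

Raw intensities are clamped at 1 and log2-transformed, quantile normalized
(every sample is forced onto the cross-sample mean empirical distribution;
ties within a sample receive the mean of the reference values at their
tied ranks), and gene-centralized (each gene's mean across samples is
subtracted).  After centralization the values are differential expression
$\Delta e$ in log2 units; the SOM is trained on these.  Centralization has
two consequences worth keeping in mind:

* sample profiles of disjoint groups become mechanically anticorrelated
  (profiles roughly sum to zero across samples), and
* a module active in a fraction $p$ of samples peaks at
  $\text{amplitude} \times (1 - p)$: the broader a module, the lower its
  centralized peak.

No variance filtering is applied by default — the portrayal approach feeds
the full transcript set into the map.

## The batch SOM

Genes are data points in sample space with Euclidean distance.  The map is
a `grid_rows` x `grid_cols` lattice of prototype vectors ("metagenes",
default 50 x 50 = 2500).  Each epoch assigns every gene to its best
matching unit (BMU) and recomputes all prototypes as Gaussian
neighborhood-weighted means; the radius decays linearly from
`max(grid)/2` to 0.5, so late epochs approximate a k-means refinement
while early epochs enforce topology.  Initialization is deterministic on
the plane of the first two principal components (+-2 sd across the grid),
with a seeded random fallback for degenerate inputs.  Batch (rather than
online) updates make training deterministic given the input and seed.

The metagene value of a node is the prototype component itself, not a
post-hoc average of mapped genes; this keeps empty nodes defined (they
interpolate their neighborhood).  Empty and sparsely occupied nodes
adjacent to a dense module patch therefore carry smoothed, near-patch
values — a property that matters for spot segmentation (below).

Default epochs are 50; the quantization error is monitored per epoch and
is non-increasing over the final stretch in the shipped tests.  For
interactive work a 20 x 20 or 30 x 30 grid resolves a 5,000-gene cohort
well; 50 x 50 reproduces full-scale portrayal.

## Portraits, summary maps and spot modules

A sample portrait is the sample's prototype column reshaped to the grid;
group portraits average member samples and difference portraits subtract
group means.  The over-expression summary map takes each node's maximum
over all samples.  Spots are detected by thresholding this map at a
quantile (default 0.92) and taking 8-connected components of at least
`min_size = 5` nodes, labelled `A`, `B`, ... by decreasing peak height.

Two deliberate choices:

* **8-connectivity**: portraits are smooth; 4-connectivity fragments
  ridges.
* **Quantile threshold 0.92**: the threshold must leave room for the
  major modules.  Five 100-gene modules in a 5,000-gene cohort place
  roughly 6--8% of the map inside module footprints, so a 0.95 cut cannot
  contain all five by a simple capacity argument
  ($0.05 \cdot n_\text{nodes}$ is smaller than the footprint mass); 0.92
  keeps all of them while still excluding the background.

Known limitation: when two modules are co-active in the same samples
(such as a shared disease module next to a severity-specific one), the
summary map has no valley between their patches — interpolating nodes are
high in exactly the co-active samples — and a single global threshold can
merge them into one component.  Together with boundary fuzz (smoothing
halos, partially occupied perimeter nodes) this bounds how sharply a
detected spot can match a planted module's BMU footprint; in the shipped
synthetic conditions the per-module node-Jaccard against the majority-rule
footprint averages about 0.8 with a minimum around 0.6.  The activation
rule for spot statistics (a spot is active in a sample when at least half
its nodes rank in the sample's top decile) is scale-invariant by
construction.

Under-expression spots are not segmented separately: by centralization
symmetry they are the over-expression spots of the complementary groups.

## Class discovery

Samples are clustered by Ward linkage (`ward.D2`) on Euclidean distances
between metagene columns.  Cluster quality uses the correlation-difference
silhouette: per sample, the mean Pearson correlation to its own cluster
(self excluded) minus the best mean correlation to any other cluster.
This is intentionally *not* the classical silhouette — there is no
denominator, scores live in $[-2, 2]$, and members of singleton clusters
score 0 by convention.  `choose_k()` scans k = 2..8 and takes the maximum
mean score, breaking ties toward smaller k.  A sample-SOM (the same
trainer applied to samples as data points in metagene space) provides the
2-D diversity map.

Because the no-denominator silhouette rewards strongly negative
between-block correlations, it prefers coarse splits on hierarchically
organized cohorts; four groups win only when each group carries a strong
private expression program.  The synthetic generator plants exactly that
structure (see below).

## Gene-set Z-scores and enrichment

For a set $S$ with $N$ members in the universe, the per-sample score is

$$\mathrm{GSZ}_j = \sqrt{N}\,
  \frac{\overline{\Delta e}_{S,j} - \overline{\Delta e}_{\cdot,j}}
       {\mathrm{sd}_g(\Delta e_{g,j})}$$

— a one-sample z-statistic of the set mean against the whole-transcriptome
distribution of that sample.  Random sets on uncorrelated data are
standard-normal calibrated (checked in the tests); the whole universe
scores exactly 0, and the score is invariant to rescaling all
$\Delta e$ (the denominator rescales too).  Group-level scores are means
of per-sample scores.  Spot enrichment uses the one-sided (greater)
hypergeometric tail — only over-representation is meaningful in a
co-expression spot — with Benjamini-Hochberg adjustment across sets within
each spot; two-sided Fisher tests serve the accumulation/depletion calls
of arbitrary gene lists and the clinical contingency tables.

## Marker discovery

All ranking uses the midrank Mann-Whitney AUC (ties count 1/2).  AUC maps
evaluate every metagene profile against a binary phenotype; the down-map
is the mirror `1 - up`.  Signature ROC curves score samples by the mean
member expression — averaging compensates gene-level noise, which is why a
module-average metagene can classify perfectly while no single member gene
does.  Differential expression uses Welch's unequal-variance t-test with
BH adjustment (the fold change is the class-mean difference of log2
values, so `t` and the fold change share signs); under the null its
p-values are uniform (Kolmogorov-Smirnov-checked).  `select_markers()`
keeps genes whose BMU reaches a node-level AUC cutoff and ranks them by
their own single-gene AUC.

## Immune deconvolution and trajectories

Cell fractions are estimated by non-negative least squares
$\min \|S f - m\|,\ f \ge 0$ on the genes shared between the mixture and a
linear-scale signature matrix, followed by normalization to a unit
simplex.  This is a transparent, exactly testable substitute for
support-vector-regression deconvolution: noiseless mixtures in the
signature's column space are recovered to numerical precision, estimates
are invariant to the mixture's scale, and at 10% multiplicative noise the
mean absolute error on 22 cell types stays well below 0.05.  Log-scale
matrices are de-logged first; centralized matrices are refused because
their values are no longer abundances.  No goodness-of-fit p-value or
absolute-abundance mode is provided.

Trajectories along villous atrophy order samples by the GSZ of a
lower-crypt proliferation signature and LOESS-fit each cell type's
fraction (tricube weights, degree 1, span 0.75, no robustness iterations;
duplicate positions are collapsed by averaging).

## Pathway signal flow

Pathways are signed directed acyclic graphs.  Node values are positive
fold changes ($2^{\text{group-mean } \Delta e}$, positive by
construction); unmapped nodes default to the neutral value 1.  In
topological order, a source's signal is its own value; every other node
multiplies its value by the sum over incoming edges of the parent signal
(activation) or its reciprocal (inhibition).  Summation over multiple
parents preserves monotonicity in the inputs; cyclic topologies are
rejected.  Agreement with a recursive reference evaluation is verified on
randomly generated DAGs.

## The synthetic cohort generator

The generator emulates the statistical structure the pipeline assumes,
with four groups (`R`, `M`, `CD-L`, `CD-H`; 17/9/8/12 samples):

* **Five co-expression modules** `A`--`E` (100 genes each).  Private
  modules (`A` in R, `B` in M, `C` in CD-L, `E` in CD-H) are 2.8 log2
  units up in their group and mildly repressed (-1.0) in the neighbouring
  group — group-defining programs are antagonistic, keeping the four
  groups mutually distinct rather than a two-block hierarchy.  The shared
  module `D` is up in both CD groups at 3.9 so that its *centralized*
  peak (which shrinks with the active-sample share) matches the private
  modules.
* **Per-probe dropout** (default 0.4): in each active sample a module
  probe misses its signal with this probability, as bead-array probes do.
  Dropout is what makes single member genes imperfect classifiers while
  the module average classifies cleanly.
* **An antagonistic crypt gradient**: two 80-gene blocks load with
  opposite signs (weights 0.15--0.3) on a latent atrophy score that
  increases from R to CD-H, with slight overlap between neighbouring
  groups.
* **Graded background co-expression**: 35% of background genes load
  weakly (0.1--0.3) on two random structure factors; real co-regulation is
  graded, and these genes populate the map regions between module
  patches.
* **An immune mixing layer**: a 22-cell-type signature with 8 exclusive
  markers per type; mixing proportions follow fixed base abundances
  modulated by atrophy-linked trends (activated T cells and M0/M1
  macrophages up; resting NK, M2 macrophages and resting dendritic cells
  down) plus lognormal jitter, added on the linear intensity scale.
* **Per-sample distortions**: multiplicative intensity factors
  (sd 0.2 log2 units), removed by quantile normalization downstream.
* **Phenotypes**: serology positivity, Marsh stage, sex and age are
  sampled from the per-group empirical rates of the clinical table shipped
  in `inst/extdata`, so their contingency with group reproduces the
  expected Fisher-test pattern; diagnosis counts per group are fixed.

Expression is generated in log2 space around a baseline of 7 (immune
marker rows start at 5 so infiltration dominates them) and exponentiated,
so preprocessing is genuinely exercised.  All randomness flows through one
seed; identical configurations and seeds are bit-identical.

What the generator does **not** emulate: probe-level bead data, batch or
site effects, correlated gene-gene noise beyond the planted structure,
realistic dynamic-range compression, or non-coding RNA biochemistry.
Passing recovery tests on this cohort therefore demonstrates correctness
of the algorithms under controlled conditions, not performance on real
biopsies.

## Reference problem sizes

The shipped tests and the acceptance script use a 5,000-gene, 46-sample
cohort on a 30 x 30 map with 50 epochs (about 15 s to train), a 50 x 50
structural check on a 500-gene matrix, 20 deconvolution replicates at 10%
noise, 1,000 random sets for GSZ calibration, 2,000 null genes for the
volcano calibration and 200 random lists for the spot-association
false-positive rate.  Module-level unit tests run on a compact 1,500-gene
cohort and a 15 x 15 map.

## Numerical conventions

Node indices are 1-based row-major with node (1,1) rendered top-left.
Ties in BMU assignment break toward the lower node index; AUC ties count
1/2; the quantile threshold of spot detection is strict (a constant map
yields no foreground); zero-variance profiles are excluded from
correlation edges with a warning and refused in the sample correlation
matrix; singleton clusters score 0 in the silhouette; all-zero
contingency tables give p = 1; Fisher odds ratios use the unconditional
`ad/bc` convention (`Inf` when `bc = 0`).
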