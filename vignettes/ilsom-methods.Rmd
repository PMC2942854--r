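---
title: "Methods: SOM integration of transcript and metabolite profiles from introgression lines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SOM integration of transcript and metabolite profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ilsom)
```

## The problem and the model

Introgression-line (IL) panels — genotypes carrying defined chromosomal
segments from a wild relative in a domesticated background — expose
quantitative variation in both gene expression and metabolite
accumulation. The analytical question is not differential expression
against a single contrast but *co-variation across genotypes*: which
transcripts and metabolites move together (or in opposition) over the
panel, since co-clustered entities are candidates for shared regulation
(guilt-by-association).

`ilsom` addresses this with a two-dimensional self-organizing map
(SOM). Each molecular entity contributes a pattern
$\mathbf{x} \in \mathbb{R}^P$ of normalized log ratios, one component
per IL. Neurons $j = 1,\dots,K$ on a rectangular grid carry codebook
vectors $\mathbf{w}_j$; a pattern activates its best-matching unit
(BMU), the neuron minimizing the Euclidean distance
$d(\mathbf{x}, \mathbf{w}_j) = \lVert \mathbf{x}-\mathbf{w}_j\rVert_2$.
Unlike U-matrix-style SOM analysis, clusters are read directly off
neuron (or pooled-neighborhood) membership, so no post-hoc cluster
boundary detection is required.

### Preprocessing

Measurements enter as replicate-level relative ratios per (entity,
genotype). The pipeline (`profile_dataset_from_replicates()`):

1. **Replicate filter and averaging** — a genotype is valid for an
   entity only with at least 2 detected replicates (configurable); the
   value is $\log_{10}$ of the mean ratio (mean-then-log). Genotypes
   failing the filter become **pseudo-zeros**: explicitly missing, held
   in a validity mask, never silently treated as 0.
2. **Magnitude filter** — metabolites are kept only if
   $\max_{\text{valid } i} |\log R_i| > 0.1$. The criterion is applied
   to the absolute value because down-regulation is as informative as
   up-regulation, and per-entity (not per-genotype) since one strong
   response anywhere justifies keeping the profile. Transcripts are
   filtered upstream at the array level instead
   (`detect_nonexpressed_spots()`: a spot is non-expressed when its
   foreground mean is below background mean + 2 background sd).
3. **Unit normalization** — each pattern is scaled so that the sum of
   squared *valid* components equals 1:
   $x_i = \log R_i \big/ \sqrt{\sum_{j \in \text{valid}} (\log R_j)^2}$.
   The square root in the denominator is what makes the stated
   unit-sum-of-squares property hold; dividing by the raw sum of
   squares would not. This removes amplitude so clustering compares
   response *shapes* across genotypes.
4. **Inversion augmentation** — every pattern gains a sign-inverted
   twin, interleaved original/inverted. Direct relations
   (&uarr;t&harr;&uarr;m) and cross relations (&uarr;t&harr;&darr;m)
   then both surface as plain co-location: an anti-correlated pair
   co-clusters through one member's twin.

### Map training

Initialization is by principal components (`init_pca()`): codebooks lie
on the regular grid spanned by the first two PCs, scaled by the
component standard deviations, centered on the data mean. This makes
training deterministic and independent of pattern input order. Two
numerical details matter: PC signs are made canonical (largest-magnitude
loading positive), because SVD sign indeterminacy would otherwise make
the layout depend on row order; and rank-deficient data fall back to a
PC1-only layout with a warning. Pseudo-zero entries enter the PCA as 0,
their placeholder value at the data mean of inversion-closed data.

Training is the **batch** algorithm: per epoch, all patterns are
assigned to BMUs, then every codebook is replaced by the
neighborhood-weighted mean
$\mathbf{w}_j \leftarrow \sum_i g_{b(i)j}\,\mathbf{x}_i \big/ \sum_i g_{b(i)j}$
with the Gaussian neighborhood $g_{ij} = e^{-\delta_{ij}^2/2r^2}$,
where $\delta_{ij}$ is the grid distance. Distances and means are
computed per component over valid entries only — missing values are
excluded, never imputed. A component with zero total neighborhood
weight keeps its previous value. At $r = 0$ the kernel degenerates to
winner-takes-all and one epoch is exactly one Lloyd k-means step; the
test suite exploits this as an independent oracle, and tracks the mean
squared quantization error, which is non-increasing in that regime.

Defaults (all exposed in `som_config()`): 40×40 rectangular lattice
(hexagonal available), 50 epochs, radius decaying linearly from
$\max(\text{rows},\text{cols})/4$ to 1 (floored at 1 so the schedule is
never increasing on small maps). The map size suits datasets on the
order of $10^3$ patterns; for toy datasets a proportionally smaller map
avoids over-parameterization (see *Limitations*). Unit numbering is
1-based column-major; BMU ties break to the lowest unit index — a
deterministic, documented choice that only matters at exact ties.

### Map analysis

* **Composition** (`classify_composition()`): units are red
  (transcripts only), blue (metabolites only) or black (mixed). With a
  visualization neighborhood $V_n > 0$, membership is pooled over all
  units within Chebyshev radius $V_n$ (the square ring matching the
  grid display) before counting; pooling is monotone — it can only add
  kinds, never turn a mixed unit pure.
* **Cohesion** (`cohesion()`): intracluster variance
  $\bar C_j = \frac{1}{|\Omega_j|}\sum_{\mathbf{x}_i \in \Omega_j}
  \lVert \mathbf{x}_i - \mathbf{w}_j\rVert^2$; values near 0 mean
  compact nodes. With pseudo-zeros the squared distance runs over valid
  components and is rescaled by $P/n_{\text{valid}}$ so partially
  observed members stay comparable. Empty units have *no* cohesion
  (reported absent, not 0), and the global compactness
  $\bar C = \frac{1}{k}\sum_j \bar C_j$ averages over the $k$
  *nonempty* units — the divisor is a genuinely open choice and this
  reading is the one under which every term is defined.
* **Three-color maps** (`three_color_map()`): per genotype dimension, a
  nonempty unit is green if some member value exceeds the member mean
  plus one (population) standard deviation, else gray if some member
  falls below mean minus one sd, else white. Green is tested first: the
  two available phrasings of the gray rule conflict, and only the
  "below mean − sd" reading yields the three-way green/gray/white
  partition; single-member units (sd 0) are white. The classification
  is invariant under positive rescaling of a genotype dimension.
* **Symmetry** (`symmetry_report()`): on inversion-closed data the
  mean is exactly zero and a converged map is negation-symmetric — a
  pattern's inverted twin lands on the 180°-rotated grid position
  (rows+1−r, cols+1−c). The report gives the fraction of exact mirror
  pairs; deviations indicate incomplete convergence or tie-breaking
  asymmetries.
* **Pseudo-zero units, chromosome subsetting, search** — direct
  queries over the assignment; chromosome tags parse from IL names like
  `"12-1-1"` (leading token).

### Annotation

Lookups are local tab-separated tables (probe code → Arabidopsis/
Unigene IDs; metabolite → KEGG compound and pathways), keeping the tool
network-free and the linkage testable; users export the mappings once
from KEGG or their array annotation release. Annotation is pure
decoration: membership, counts and cohesions are byte-identical with
and without it. The bundled tables under `inst/extdata/` carry
`synthetic_` in their names: they are constructed examples for the demo
entity names, not real database exports.

## The synthetic-data generator

`synth_spec()` / `synth_generate()` emulate an IL profiling study well
enough to exercise every pipeline stage: 21 ILs named by chromosome
segment (chromosomes 1, 2, 3, 5, 8, 10, 11, 12; four lines on
chromosome 12), 1385 transcripts and 71 metabolites by default —
matching the scale of a real tomato IL fruit study — of which `G = 6`
planted groups (5 transcripts + 2 metabolites each) share latent,
mutually orthogonalized genotype profiles with within-group correlation
0.95; one third of the groups anti-correlate their metabolites
(cross relations). Replicates (3 per entity × genotype) carry Gaussian
noise of sd 0.05 on the log10 scale (≈12% CV, typical technical
replicate noise) and are dropped independently with probability 0.05,
which creates pseudo-zeros through the ≥2-replicate validity rule. All
randomness flows through one seed; generation restores the caller's RNG
state.

What the generator does **not** emulate: spatial array artifacts and
print-tip effects (inputs begin at relative ratios), correlated
missingness (real pseudo-zeros concentrate in specific genotypes),
heavy-tailed replicate noise, and background correlation structure
between "unstructured" entities. Passing recovery tests therefore show
that the machinery finds planted co-regulation of realistic strength at
realistic scale — not that every biological signal in real data would
be recovered.

## Test and validation design

Problem sizes in the suite are deliberately modest: unit oracles run on
maps of ≤ 25 units and ≤ 50 patterns where brute force is exact and
instant; the two end-to-end properties (mirror symmetry, planted-group
recovery) train the default 40×40 map on a 200-pattern
(P = 10, 100 entities) and a 2912-pattern (paper-scale) dataset
respectively, each in well under a minute. Group recovery is scored as
the fraction of within-group pairs whose sign-aligned BMUs share a
radius-1 pooling neighborhood (grid Chebyshev distance ≤ 2), the
literal reading of $V_n$ pooling; at the default scale the planted
groups in fact land on same-or-adjacent units.

## Limitations

* The 40×40 default map over-parameterizes small datasets (hundreds of
  patterns): tight clusters then spread over small patches, and
  radius-1 pooling captures less of each group. Scale the map with the
  data (a few patterns per unit, as in the figures' 25×25 and 20×20
  maps for subsets) when working at toy scale.
* Mirror symmetry is exact only in exact arithmetic; floating-point
  accumulation order can displace a handful of pairs on large maps.
  The report quantifies this rather than assuming it.
* `chromosome_subset()` restricts dimensions for display; the subset is
  no longer unit-normalized, so it should not be re-trained without
  re-normalization.
* The unit normalization is undefined for all-zero or all-invalid
  patterns; such entities must be (and are) dropped upstream.
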