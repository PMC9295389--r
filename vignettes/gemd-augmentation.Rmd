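---
title: "Graph-EMD augmentation of morphometric brain networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-EMD augmentation of morphometric brain networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(gemdaug)
```

## The problem

Cohorts in pediatric neuroimaging are small: a typical case-control study
has a few dozen subjects, while the per-subject representation — here a
structural-connectivity (SC) matrix over a few hundred cortical regions —
has tens of thousands of entries. Deep classifiers overfit such data
badly. `gemdaug` implements a decomposition–recombination augmentation:
each training subject's regional morphometric features are decomposed into
intrinsic mode functions (IMFs) over a brain-region graph, and artificial
subjects are synthesized by summing one IMF per frequency slot drawn from
several real subjects of the same group. The artificial subjects inherit
the group's joint structure across regions and features while being new
points in data space.

## The region graph

The $B$ regions are nodes of a weighted undirected graph. Regions $i$
and $j$ at Euclidean centroid distance $d_{ij}$ are connected when
$d_{ij} < \delta$ (strictly), with Gaussian weight

$$w_{ij} = \exp\!\left(-\frac{d_{ij}^2}{2\delta^2}\right),$$

and $L = D - W$ is the combinatorial Laplacian ($D$ the degree matrix).
Parameters that matter:

* `delta` (mm) — the edge threshold and kernel bandwidth. Default: the
  30th percentile of the pairwise centroid distances, which keeps the
  graph connected on realistic centroid clouds while staying sparse. The
  threshold is strict, so a pair at exactly $\delta$ is not connected.
* Distances are taken between 3-D centroids by default; any coordinate
  matrix can be supplied, so feature-space distances are also possible.

Disconnected graphs are allowed with a warning; every operation treats
components independently.

## Graph empirical mode decomposition

A node is a local maximum of a graph signal $x$ when its value strictly
exceeds all of its neighbors' values (minima symmetrically). Because the
comparison is strict, plateaus of exactly equal values produce no extrema;
on heavily quantized data this is a known limitation and can end the
decomposition early.

Envelopes are harmonic extensions: given the extrema set $K$, the envelope
$s$ minimizes the total graph variation $s^\top L s$ subject to
$s(K) = x(K)$. The minimizer satisfies $(Ls)(u) = 0$ at every unknown node
and is obtained from the reduced linear system
$L_{UU}\, s_U = -L_{UK}\, s_K$, solved densely per connected component (a
direct solve is exact and, at $B \le 308$, faster than iterative methods).
A component containing no extremum is filled with the mean of the known
values — a logged fallback, not an error — so decomposition proceeds on
disconnected graphs.

One IMF is extracted by sifting: repeatedly subtract the mean envelope
$z = (e_{\min} + e_{\max})/2$ from the working signal $m$ until the
envelope energy $\sum_n z(n)^2$ falls below the energy of the signal that
entered the extraction divided by `energy_ratio` (default 1000), or
`max_sift_iters` (default 50, a non-convergence guard) is reached.
Extraction stops when the residual has no extrema of one kind — a trend
over the graph — or when `max_imfs` (default 5) IMFs exist. A mode that
loses its oscillation during sifting is left in the residual rather than
stored. These two nested loops are the classical decomposition structure;
the energy criterion governs the inner loop, and both gates are exposed in
the configuration.

Properties enforced by construction and verified in the tests:

* reconstruction: extracted IMFs plus residual equal the input to 1e-8
  relative tolerance (a telescoping identity of the recursion);
* the harmonic maximum principle: envelope values stay within the range of
  their defining extrema on connected graphs;
* positive 1-homogeneity: scaling the signal by $c > 0$ scales every IMF
  by $c$.

For cohort decomposition (`decompose_cohort`), every feature column of
every subject is decomposed independently into an $M \times B \times F
\times P$ tensor. Stacks with fewer than $M$ IMFs are zero-padded in the
highest-index (low-frequency) slots, and each decomposition's residual is
folded into slot $M$. The folding is a design choice: recombined
artificial subjects then conserve total signal content, and the
reconstruction identity holds for the stored tensor itself.

## Recombination augmentation

An artificial subject is built from $M$ distinct donors of one group: a
uniformly random permutation assigns each donor one IMF slot, and the
artificial feature matrix is the sum of the assigned IMFs. One donor set
and one permutation are shared across all $F$ features (preserving
within-subject cross-feature coupling); `per_feature_donors = TRUE`
re-draws them per feature for comparison. Donors are drawn without
replacement within one artificial subject — feasible whenever each group
has at least $M$ training subjects — with a `replace` flag for smaller
cohorts. Reproducibility comes from a single seeded RNG stream consumed
sequentially; provenance (donor ids and permutation) is stored on every
artificial subject, and the experiment harness refuses to run if any
donor lies outside the training split.

The SMOTE baseline acts at the same pipeline stage on flattened
$B \cdot F$ vectors: each synthetic sample is $x + u(x_{nn} - x)$ with
$u \sim U(0,1)$ and $x_{nn}$ one of the $k$ (default 5) nearest same-group
neighbors.

## Structural connectivity

Each subject's SC matrix is the inter-regional correlation of
morphometric features: entry $(i, j)$ is the Pearson correlation between
region $i$'s and region $j$'s $F$-vectors,

$$c(x, y) = \frac{S_{xy}}{\sqrt{S_{xx} S_{yy}}}, \qquad
S_{xy} = \sum_{f=1}^{F} (x_f - \bar{x})(y_f - \bar{y}).$$

This is the single-subject morphometric-similarity construction, distinct
from across-subject structural covariance. Two conventions are explicit
configuration:

* `normalize` (default `TRUE`): feature columns are z-scored across
  regions first, because morphometric features span incommensurate units
  (mm³ volumes vs dimensionless curvature); without it the correlations
  are dominated by the largest-scale feature.
* `standardize` (default `"zscore"`): off-diagonal entries are z-scored
  within the subject using the population standard deviation, and the
  diagonal is set to 0 (self-connections carry no class information). A
  Fisher $r$-to-$z$ variant and a pass-through are provided. The
  within-subject convention removes between-subject level differences in
  overall similarity; re-applying it is idempotent.

Degenerate inputs are handled explicitly: a region with zero feature
variance gets zero correlations (with a warning), and an SC matrix whose
off-diagonals have zero variance is an error rather than a silent
division by zero.

## The classifier

The network operates directly on the $D \times D$ SC matrix with the
three connectome filter types:

* edge-to-edge (E2E): cross-shaped kernels,
  $\mathrm{out}[i,j] = \sum_k c_1[k] X[i,k] + \sum_k c_2[k] X[k,j]$;
* edge-to-node (E2N): $\mathrm{out}[i] = \sum_k c_1[k] X[i,k]$;
* node-to-graph (N2G): $\mathrm{out} = \sum_k c_2[k] v[k]$.

The architecture is E2E (4 channels) → ReLU → E2N (16) → ReLU → N2G (32)
→ dense (16) → dense (1) → sigmoid, trained with Adam
($\mathrm{lr} = 0.001$, $\beta_1 = 0.9$, $\beta_2 = 0.999$), batch size
32, 300 epochs by default. Design choices where the architecture
description leaves room:

* the output nonlinearity is a sigmoid with binary cross-entropy — the
  standard binary-classification pairing (the original connectome CNN
  literature also used regression losses);
* ReLU is applied after the N2G and first dense layers as well: three
  stacked linear maps would otherwise collapse into one;
* no dropout or weight decay by default (exposed in the configuration);
* initialization is He-scaled normal, seeded; training shuffles batches
  from a seeded stream, so CPU runs are bit-reproducible.

The implementation is a compact, fully vectorized forward/backward pass
in R; each filter is unit-tested against brute-force loop oracles, and
training is validated by overfitting a small separable fixture to 100%
accuracy and by a shuffled-label capacity probe.

## The experiment harness

`run_session` mirrors the augmentation experiment protocol: draw a
stratified fixed split (7 + 7 training subjects by default, the rest held
out), augment the training split only, compute SC for both splits, train,
and report held-out accuracy. Test subjects never donate IMFs — a
provenance check aborts the session on any violation. `run_sweep` iterates
sessions over artificial-sample counts, methods, and seeds into a tidy
table. A stratified k-fold split is also available behind `split_spec`.

## The synthetic cohort generator

The generator emulates the statistical structure the pipeline assumes,
not raw images: per-subject regions × features matrices that are smooth
over the region graph, with a group difference planted in inter-feature
covariance inside a designated region block. Its parts:

* region centroids: a Fibonacci lattice on an ellipsoidal shell with
  brain-like semi-axes (85, 70, 60 mm) and a small seeded radial jitter;
* a shared anatomical factor: one smooth random field (combination of the
  `smoothness` = 8 lowest-frequency Laplacian eigenvectors, unit
  per-region variance) loading uniformly on all features — morphometric
  features of one brain share a strong common component;
* feature-specific smooth fields at half that amplitude;
* the planted effect: a fixed block pattern expressed at subject level
  $a \sim N(1, 0.2)$, loading on features uniformly in the gifted group
  and as a $\pm$ feature-family contrast in the control group, both
  scaled by `effect_size`. The two loadings have equal per-feature
  magnitude, so all marginal variances match across groups and the groups
  differ **only** in inter-feature covariance. For $F = 2$ this reduces
  to coupling a feature pair with a group-dependent sign. This
  formulation was chosen because a pure sign flip of a zero-mean coupled
  pair is nearly invisible to row-centered correlation (SC covariance is
  invariant to feature-column sign flips except through row means), and a
  fixture must plant an effect the pipeline can demonstrably recover;
* i.i.d. Gaussian noise, `noise_sd` = 0.3 by default against unit-variance
  structure — a moderate measurement-noise regime.

With `effect_size = 0` the groups are exchangeable by construction, which
is the basis of the null-calibration test. Default sizes mirror the study
design the package targets (two groups of 15 and 14), with $B = 60$
regions as the standard test scale and $B = 308$ for full-scale shape
checks.

What passing tests on this generator do and do not show: they validate
the machinery (decomposition identities, leakage-free augmentation,
calibrated evaluation) and that augmentation does not hurt when the class
signal lives in block-structured SC patterns. They do not show that real
morphometric data contain such a planted structure, nor how large the
augmentation benefit is on any real cohort.

## Numerical choices

* Energy is the squared $\ell_2$ norm; the envelope-energy stopping ratio
  is 1000.
* Linear systems are solved with dense LU per component; interpolation is
  verified against a full KKT solve of the constrained quadratic program
  to 1e-8 on all test graphs.
* Population (n) standard deviations are used for z-scoring (features,
  SC off-diagonals); the $n{-}1$ convention cancels inside correlations.
* Extrema ties break toward "no extremum" (strict inequalities).
* Binary predictions threshold the sigmoid output at 0.5.

## Problem sizes used in the packaged experiments

The packaged tests and the acceptance script run the full pipeline at
$B = 60$ regions, 29 subjects, 50 artificial subjects per group, 60
training epochs, and 10 repeated sessions — sizes at which one session
takes seconds and the statistical claims (planted-effect recovery above
0.7 accuracy; augmentation not hurting; null calibration at 0.5) are
stable. Full-scale ($B = 308$, 300 epochs) runs use the same code paths
through the same configuration objects.

## Known limitations

* Strict extrema make the decomposition sensitive to exact ties
  (quantized data may terminate early).
* The value of $\delta$ for real centroid data is a free parameter; the
  30th-percentile default is a heuristic, not a fitted value.
* The classifier is CPU-oriented; at $B = 308$ with hundreds of
  artificial subjects and 300 epochs, training takes hours rather than
  minutes.
* Within-subject z-scoring of SC is one of several reasonable
  standardization conventions; alternatives are exposed but not
  benchmarked against each other.

## A minimal end-to-end run

```{r pipeline, eval = FALSE}
coords <- make_region_coordinates(60, seed = 2)
graph <- build_region_graph(coords)
cohort <- make_synthetic_cohort(synth_spec(B = 60, seed = 3), graph)
config <- brainnet_config(D = 60, epochs = 60, seed = 1)

res <- run_sweep(cohort, graph, n_grid = c(0L, 50L),
                 methods = c("none", "gemd"), seeds = 1:10,
                 config = config)
aggregate(accuracy ~ method, res, mean)
```
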