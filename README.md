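# gemdaug

Data augmentation for small morphometric MRI cohorts by graph empirical
mode decomposition (GEMD), with the full downstream pipeline: per-subject
structural connectivity and a connectome convolutional classifier.

## The problem

Case-control neuroimaging studies of special populations are small — a
few dozen subjects — while each subject is represented by a structural
connectivity (SC) matrix with tens of thousands of entries, so deep
classifiers overfit. `gemdaug` grows the training set with artificial
subjects that respect the joint structure of real ones:

1. **Region graph.** The B cortical regions form a weighted graph: regions
   at centroid distance d < δ are linked with Gaussian weight
   w = exp(−d²/2δ²); L = D − W is the graph Laplacian.
2. **GEMD.** Each morphometric feature (a graph signal over regions) is
   decomposed into intrinsic mode functions (IMFs) by sifting: local
   extrema are nodes strictly above/below all neighbors, envelopes are
   harmonic extensions of the extrema (minimize sᵀLs with s fixed on the
   extrema — a Dirichlet problem solved via L_UU s_U = −L_UK s_K), and the
   mean envelope is subtracted until its energy falls below the signal
   energy / 1000. Up to M = 5 IMFs per signal, zero-padded; IMFs + residual
   reconstruct the input exactly.
3. **Recombination.** An artificial subject is the sum of one IMF per
   frequency slot, each contributed by a different randomly chosen
   same-group donor (a random permutation matches M = 5 donors to the 5
   slots). A SMOTE baseline is included.
4. **Structural connectivity.** Per subject, region i and region j are
   correlated over their F = 7 morphometric values:
   c(x,y) = S_xy / √(S_xx S_yy), S_xy = Σ (x_f − x̄)(y_f − ȳ), giving a
   B × B matrix, z-scored within subject.
5. **Classifier.** A compact connectome CNN on the SC matrix:
   E2E (4 ch) → ReLU → E2N (16 ch) → ReLU → N2G (32 ch) → dense 16 →
   dense 1 → sigmoid, trained with Adam (lr 0.001, β₁ 0.9, β₂ 0.999),
   binary cross-entropy, batch 32.

A synthetic cohort generator (two groups of 15 and 14 subjects, smooth
signals over the graph, a planted group difference in inter-feature
covariance inside a region block) makes the whole pipeline testable with
no imaging data; see the methods vignette
(`vignettes/gemd-augmentation.Rmd`) for the model details and design
decisions.

## Worked example

Ten repeated sessions on the synthetic cohort with a planted effect
(B = 60 regions, 7 + 7 training subjects, 15 held out, 50 artificial
subjects per group, 60 epochs):

```r
library(gemdaug)

coords <- make_region_coordinates(60, seed = 2)   # ellipsoidal centroid cloud
graph  <- build_region_graph(coords)              # delta = 30th pct of distances
cohort <- make_synthetic_cohort(synth_spec(B = 60, seed = 3), graph)
config <- brainnet_config(D = 60, epochs = 60, seed = 1)

res <- run_sweep(cohort, graph, n_grid = c(0L, 50L),
                 methods = c("none", "gemd"), seeds = 1:10, config = config)
aggregate(accuracy ~ method, res, mean)
#>   method accuracy
#> 1   gemd     0.90
#> 2   none     0.86
```

Each row of `res` is one session (split → augment training set only →
SC → train → held-out accuracy). Here the un-augmented classifier
recovers the planted group difference at 0.86 mean accuracy, and adding
50 GEMD-recombined subjects per group raises it to 0.90 (paired
improvement +0.04, s.e. 0.023 over the 10 sessions). With
`effect_size = 0` the same pipeline sits at chance (0.51 ± 0.03),
confirming that the evaluation is leakage-free.

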