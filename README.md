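# fusecyto

Cell-type clustering for highly multiplexed in situ imaging cytometry
(IMC, MIBI-TOF, CODEX, seqFISH) expression matrices, built around one
observation: the technical artifacts of imaging assays — staining
intensity drifting across images and tissue regions — act multiplicatively
on a cell's marker profile, so correlation-based dissimilarities (which
ignore per-cell scaling) recover curated cell types better than Euclidean
distance, and fusing both kinds is better still.

The core pipeline:

1. **Summarize** the `N x M` cell-by-marker matrix with a batch
   self-organizing map whose grid side is chosen by a sequential
   Tracy–Widom test on covariance eigenvalues (significant components
   &rarr; prototypes).
2. **Fuse** four dissimilarity views over the prototypes — Pearson,
   Spearman and cosine (each mapped to a distance by
   `d = sqrt(2 (1 - r))`) plus Euclidean — by max-scaling each view and
   averaging.
3. **Cluster** the fused matrix with average-linkage (UPGMA) hierarchical
   clustering, cut at `k`, and project prototype labels back to cells
   through their best-matching units.

Around the pipeline: the four standard external evaluation indices
(adjusted Rand, normalized mutual information, Fowlkes–Mallows, pairwise
F-measure), six cluster-number estimators (gap, silhouette, jump, slope,
within-cluster-distance elbow, and a discriminant-projection dip-test
method with a selection-matched null), a synthetic cytometry generator
with a controllable per-cell lognormal scaling artifact, and resampling
benchmark harnesses (fixed-size and stratified).

## Worked example

```r
library(fusecyto)

# canonical recovery scenario: 5000 cells, 20 markers, 8 planted types
spec <- simulation_spec(seed = 7)
em  <- simulate_cytometry(spec)
res <- fusesom_cluster(em, k = 8, run_config(seed = 7))
evaluate_partitions(res$partition, em$annotations)
#>       ari       nmi        fm         f
#> 0.9958715 0.9947227 0.9963873 0.9963873
res$grid_side      # chosen by the eigenvalue test
#> [1] 6

# why correlation metrics matter: add per-cell intensity-scaling
# artifacts (lognormal, sdlog 0.4) and cluster cells under one metric
spec_art <- simulation_spec(n_cells = 600, n_markers = 12, n_types = 4,
                            mean_separation = 6, cell_scaling_sdlog = 0.4,
                            seed = 1)
tab <- scaling_artifact_experiment(spec_art, seeds = 1:5,
                                   metrics = c("pearson", "euclidean"))
aggregate(score ~ metric, tab[tab$index == "ari", ], mean)
#>      metric       score
#> 1 euclidean 0.002820181
#> 2   pearson 0.978448942

# how many clusters would we have picked blind? (prototype-level)
spec4 <- simulation_spec(n_cells = 2000, n_markers = 12, n_types = 4,
                         mean_separation = 8, seed = 7)
em4  <- simulate_cytometry(spec4)
res4 <- fusesom_cluster(em4, k = 4, run_config(seed = 7, grid_side = 10))
discriminant_k(res4$som$prototypes, seed = 7)$k_hat
#> [1] 4
```

The same scaling artifact that drops Euclidean clustering of cells to
chance level (ARI 0.003) barely touches Pearson-based clustering
(ARI 0.978): the artifact rescales whole profiles, which destroys
Euclidean geometry but leaves profile correlations intact. The
discriminant estimator recovers the planted number of types from the SOM
prototypes alone.

A thin command-line wrapper over the same functions ships in
`inst/cli/fusecyto`:

```sh
fusecyto simulate --n 20000 --markers 20 --types 8 --seed 1 --out sim.csv --truth truth.csv
fusecyto cluster --input sim.csv --k 8 --seed 42 --out labels.csv
fusecyto estimate-k --input sim.csv --method discriminant
fusecyto evaluate --pred labels.csv --truth truth.csv
```

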