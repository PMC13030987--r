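# spatcube

Spatial statistics for 3D cell distributions in large fluorescence images,
bone marrow in particular. The package picks up where a 2D object detector
leaves off: it takes per-layer bounding-box detections of stained cells
(e.g. leukemic blasts, cytotoxic T cells, megakaryocytes), reconstructs 3D
cell locations, and quantifies how each population is organised in space and
how populations relate to each other. It is written for imaging groups who
can produce reliable 2D detections at scale but need a statistical pipeline —
not more segmentation — to turn tens of gigabytes of boxes into defensible
statements like "this cell type is concentrated in a few dense foci and that
one is excluded from them".

## What it computes

Given per-layer boxes, `aggregate_boxes()` links same-class boxes across
layers greedily (largest/brightest first; a box is absorbed by seed `q` when
its center lies within half the seed diameter `d/2`). `build_grid()` then
divides the volume into θ-sided cubes (default 45 µm) holding per-class cell
counts, with face-adjacency neighborhoods (7 cubes including the center).
On that grid:

* **Moran's I** per cell type, with binary face-adjacency weights
  φᵢⱼ = 1{dᵢⱼ ≤ θ}:

  I = n · Σᵢ≠ⱼ φᵢⱼ (aᵢ − ā)(aⱼ − ā) / [ Σᵢ (aᵢ − ā)² · Σᵢ≠ⱼ φᵢⱼ ]

  (> 0 clustered, ≈ 0 random, < 0 dispersed; permutation-null mean
  −1/(n−1)).
* **Density clustering**: a cube whose 7-cube neighborhood mean strictly
  exceeds the third quartile of that class's counts is marked (with its
  neighbors) high-density; face-connected marked cubes form clusters,
  numbered by decreasing cell content.
* **Cluster-vs-surround permutation tests**: for each cluster C and its
  face-adjacent surround, M = |mean(a_C) − mean(a_surround)| for a second
  cell type, Monte Carlo permutation p-values with the add-one estimator,
  Holm–Bonferroni corrected across clusters.
* **Presence logistic models**: odds of a cube composition (e.g. "T cells
  but no megakaryocytes") inside versus outside dense regions, with
  closed-form-verified single-predictor fits and separation flagging.
* **Quartile neighborhoods**: every cube binned by reference-class density
  quartile × presence/absence of two other classes — 16 composition
  categories.

A synthetic tissue module (`simulate_cells()`, `slice_to_boxes()`) generates
ground-truth configurations (Poisson, Thomas-cluster, hardcore processes),
slices them into per-layer boxes by the sphere-chord rule and injects
detection noise, so the entire pipeline is testable without microscope data.
An evaluation module (`match_boxes()`, `precision_recall()`,
`count_comparison()`) benchmarks detections by IOU matching and average
precision, and compares predicted versus true per-region cell counts.

## Worked example

```r
library(spatcube)

cal   <- calibration(z_step = 5)                       # 5 µm z-step
truth <- simulate_cells(default_class_specs(),         # ~5000/500/100 cells
                        volume = c(500, 500, 500), seed = 7)
boxes <- slice_to_boxes(truth, cal, noise_model(miss_rate = 0.05), seed = 8)
cells <- aggregate_boxes(boxes, cal)
grid  <- build_grid(cells, cube_size = 45)
graph <- neighbor_graph(grid)

morans_i(grid, graph)
#> # A tibble: 3 × 4
#>   cell_class       I     n sum_weights
#>   <chr>        <dbl> <int>       <dbl>
#> 1 AML        0.592    1728        9504
#> 2 CTL        0.0822   1728        9504
#> 3 MK         0.00950  1728        9504
```

The clustered blast-like class scores high autocorrelation, the weakly
clustered T-cell-like class sits near zero, and the hardcore-random
megakaryocyte-like class is indistinguishable from randomness — the
qualitative ordering the statistics are built to expose.

```r
clus <- density_clusters(grid, graph, "AML")
glance(clus)
#> # A tibble: 1 × 6
#>   cell_class quantile q3_threshold n_high_density n_clusters largest_cluster_count
#> 1 AML            0.75            1           1135          1                  7267

perm <- permutation_test(grid, cluster_regions(clus, graph), "CTL",
                         m = 10000, seed = 9)
dplyr::select(perm, cluster_id, observed_M, p_raw, p_adjusted)
#> # A tibble: 1 × 4
#>   cluster_id observed_M  p_raw p_adjusted
#> 1          1      0.100 0.0963     0.0963
```

Here the dense blast region is found, and the permutation test correctly
fails to reject independence of the T-cell counts from it — the simulator
places the classes independently, so this is the expected null behaviour.
`presence_glm(grid, clus, c("CTL", "MK"))` and
`quartile_neighborhoods(grid, "AML", c("CTL", "MK"))` complete the picture;
each result type has `tidy()`/`glance()` and `autoplot()` methods.

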