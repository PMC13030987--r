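---
title: "Methods: cube-based spatial statistics for 3D cell maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cube-based spatial statistics for 3D cell maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

spatcube analyses the spatial organisation of cell populations in large 3D
fluorescence images after a 2D object detector has already done its work. Its
input is the detector's output — per-layer bounding boxes with class labels
and confidences — and its product is a set of spatial statistics over a cube
discretization of the tissue: global autocorrelation per cell type, contiguous
high-density regions, cluster-versus-surround abundance tests, composition
odds ratios and a quartile-neighborhood classification. This vignette explains
each model, its assumptions, the tunable parameters, and the numerical and
design choices behind the implementation.

## From 2D boxes to 3D cells

A cell imaged in a z-stack appears as a run of roughly concentric boxes on
consecutive layers. `aggregate_boxes()` reconstructs cells greedily: boxes of
each class are ordered by maximum box diameter (descending), then mean
fluorescence intensity, then confidence; the first unassigned box seeds a cell
with diameter `d = max(width, height)` and center `q` (layer index times the
z-step); every unassigned same-class box whose center lies strictly closer
than `d / 2` to `q` is absorbed, and the procedure repeats until every box
belongs to a cell. Intensity takes part only in the *ordering* — no brightness
threshold exists anywhere, so dim cells aggregate exactly like bright ones.

Three points in this rule were genuinely open and are fixed as follows:

* **Distance.** The absorption distance is 3D Euclidean by default
  (`distance_mode = "euclidean3d"`), which removes same-layer duplicates from
  overlapping mosaic tiles and links stacked slices of one cell with a single
  rule. A stricter `"xy_plus_z_window"` mode (lateral distance `< d/2` *and*
  axial distance `< d/2`) is available behind the flag.
* **Tie-breaks.** The named ordering keys do not define a total order, so the
  implementation breaks residual ties on intrinsic box fields (x, y, layer,
  width, height, confidence). This makes the output invariant to the order in
  which boxes arrive from the reader, which a positional identifier would not.
* **Strictness.** The inequality is strict: a box at exactly `d/2` is not
  absorbed. Boxes need not occupy consecutive layers, so one missed detection
  inside a cell does not necessarily cut it in two.

The geometry has a consequence worth knowing. With z-step `s`, a spherical
cell of diameter `D` is sliced into boxes at axial offsets up to `D/2` from
its center; the seed is the largest (most central) box. All slices of one cell
are guaranteed to fall within `d/2` of the seed only when
`sqrt((D/2)^2 - (s/2)^2) > s` and `D < 3 s`, i.e. for `s = 5` µm when
`11.2 < D < 15` µm. Thinner cells can split into one cell per slice and larger
cells can shed their outermost slice when the stack samples them
unfavourably. This is a property of the published rule, not of this
implementation; the parameter-recovery tests therefore use diameters inside
the safe band, while the default simulator presets use realistic diameters
and accept the measured split rate.

## The cube grid

`build_grid()` divides space into cubes of side `theta` (default 45 µm; 55 µm
is a commonly used coarser alternative). A cell at position `p` goes to index
`floor((p - origin) / theta)` per axis with half-open intervals. Each cube's
spatial coordinate `(u, v, z)` is the midpoint of its lowest z-plane,
`origin + ((ix + 0.5), (iy + 0.5), iz) * theta`. The grid origin defaults to
the componentwise minimum of the data (an explicit image origin can be given
instead); a coordinate below the origin is an error rather than a silent
clamp. A marrow mask — per-cube boolean table or a voxel label image
downsampled by majority vote (`mask_from_labels()`) — excludes cells outside
the tissue; cubes partially covered by data are kept, because cells, not
cubes, are the unit of exclusion.

Two in-mask cubes are neighbors when they share a face, so an interior cube
has a 7-cube neighborhood including itself. All downstream statistics use
these symmetric 0/1 weights.

## Moran's I

For class counts \(a_i\) over the \(n\) in-mask cubes,

\[
I = \frac{n \sum_{i \ne j} \varphi_{ij} (a_i - \bar a)(a_j - \bar a)}
  {\bigl(\sum_i (a_i - \bar a)^2\bigr)\bigl(\sum_{i \ne j} \varphi_{ij}\bigr)},
\qquad
\varphi_{ij} = \mathbf 1\{d_{ij} \le \theta\},
\]

with \(d_{ij}\) the centroid distance, which for a cube grid reduces to the
face-adjacency indicator. Positive values mean cells aggregate in common
areas; values near zero indicate randomness; negative values over-dispersion.
Under random permutation of the counts the expectation is \(-1/(n-1)\), which
the test-suite verifies by Monte Carlo alongside an exact comparison with a
brute-force double-loop evaluation (relative agreement demanded at 1e-12).
Degenerate inputs — constant counts, an edgeless graph, fewer than two cubes —
raise explicit errors instead of returning NaN.

## Density clustering

`density_clusters()` marks dense neighborhoods against the third quartile of
the per-class counts over all in-mask cubes, zeros included, computed with
R's default type-7 linear interpolation. For each in-mask cube, if the mean
count over the cube and its face neighbors *strictly* exceeds the threshold,
the cube and all its neighbors are marked high-density; clusters are the
face-connected components of the marked set, labelled in decreasing order of
the total cell count they contain (ties to the lowest cube index). The
quantile convention and the strict inequality are stated deliberately: tiny
grids are sensitive to both, and the worked examples in the tests pin them
down.

One degeneracy deserves emphasis. When more than a quarter of the cubes are
empty for a class, the threshold collapses to zero, and then *every*
neighborhood containing a single cell is dense; isolated cells produce
plus-shaped clusters, and because marking extends two steps from each
occupied cube, moderately sparse classes can percolate into one large
low-density "cluster". Cluster counts for sparse classes should therefore be
read with care, and raising `quantile` is a reasonable sensitivity check.
The cluster count is a resolution-dependent summary in any case; the
robustness property actually enforced by the acceptance tests is that
clusters found at a coarser cube size sit on top of clusters found at the
finer one.

## Cluster-versus-surround permutation tests

For each cluster \(C_\tau\), the surround \(C_\tau^c\) is the set of in-mask
cubes sharing a face with a member. By default cubes belonging to *any*
dense cluster of the reference class are excluded from the surround, so it
represents non-dense tissue; `exclude = "focal"` relaxes this. A cluster with
an empty surround is emitted as an explicit untestable record — never as
p = 1.

The statistic is \(M(A) = |\operatorname{mean}(a_{C_\tau}) -
\operatorname{mean}(a_{C_\tau^c})|\) for the tested class's counts. Under the
null that membership is exchangeable, the pooled counts are re-partitioned
into groups of the original sizes; `perm_mean_test()` draws `m` random
partitions (default 500,000) and estimates the p-value with the add-one
estimator \((1 + b)/(1 + m)\), which can never be exactly zero. Because M is
already an absolute difference, its upper tail *is* the two-sided test; this
interpretation is stated rather than silently assumed. An exhaustive mode
enumerates all \(\binom{n}{k}\) partitions when that count is below a
configurable bound and returns the exact tail proportion. Seeded runs are
bit-reproducible; the suite checks Monte Carlo convergence to the exhaustive
value and the approximate uniformity of the null p-value distribution
(Kolmogorov–Smirnov over 500 simulated null datasets).

Raw p-values are Holm–Bonferroni adjusted (`stats::p.adjust`) across all
testable clusters for one tested class — that family matches how the test is
used: one comparison per reference-class cluster.

## Presence/absence logistic models

`presence_glm()` fits, per composition, a binomial GLM with logit link:
response = "cube lies in a dense reference-class cluster", predictor = "cube
matches the composition" (first class only, second class only, or both). The
three panels are three separate single-predictor models, matching the
presence/absence wording of the procedure rather than one multi-predictor
fit. With a single binary predictor the maximum-likelihood coefficient equals
the closed-form log odds ratio of the 2×2 table; the IRLS fit (epsilon 1e-10,
max 100 iterations) is required by the tests to agree with it to 1e-8.
Complete or quasi-separation — a zero cell in the 2×2 table, non-convergence,
or a coefficient beyond ±20 — is flagged and reported as non-finite
estimates, never as a fabricated large number.

## Quartile neighborhoods

`quartile_neighborhoods()` bins every in-mask cube into quartiles of the
reference-class count (type-7 edges at Q1, Q2, Q3; a count equal to an edge
goes to the *lower* bin) and crosses the bin with the presence (count > 0) of
two other classes, yielding a fixed factor of 16 categories that partitions
the cubes exactly. With mostly-empty reference counts several bins can
coincide (all edges zero), in which case the lower-bin rule sends tied cubes
to bin 1 — the categories remain well defined.

## The synthetic tissue model

`simulate_cells()` draws cell centers per class from one of three processes
in a box volume: homogeneous Poisson (CSR), a Thomas cluster process (Poisson
parents, Poisson-distributed offspring displaced by isotropic Gaussian
noise), and a hardcore-thinned CSR enforcing a minimum pairwise separation.
Parents of the Thomas process are drawn in a window dilated by 4 sigma so the
retained pattern keeps the stationary intensity kappa times mu inside the
volume instead of thinning out near the faces. `slice_to_boxes()` then images
the cells as spheres at the configured z-step: a cell of diameter D produces
on every plane within D/2 of its center a square box with the chord side
`2 * sqrt((D/2)^2 - offset^2)`, after which the noise model applies center
and size jitter, drops boxes at the miss rate, and adds low-confidence
spurious boxes at a per-area rate. Everything is bit-reproducible under a
seed.

The default presets emulate the regimes of leukemia-infiltrated marrow at
realistic scale — in 500³ µm³: an abundant, strongly clustered blast-like
class (~5,000 cells in ~10 dense foci; Thomas, sigma 25 µm, diameter 13 µm),
a sparse, weakly clustered T-cell-like class (~500 cells; Thomas, sigma
80 µm, diameter 9 µm), and a rare, large, near-randomly placed
megakaryocyte-like class (~100 cells; hardcore, separation 30 µm, diameter
28 µm). The foci of the clustered class are deliberately few, dense and
well separated, the regime in which distinct high-density clusters exist at
all; closely spaced diffuse foci merge into a single percolating cluster
under the quartile rule (see above).

What the simulator does *not* emulate — and what passing tests therefore do
not certify about real data: cells are spheres (real megakaryocytes are
large and irregular, but only centers and maximum diameters reach the
statistics); classes are placed independently, so there is no built-in
exclusion or attraction between cell types; brightness carries no spatial
structure; there are no stitching artifacts, optical aberrations or
depth-dependent signal loss; and detection errors are independent per box,
unlike a real detector's spatially correlated failures.

## Evaluation

`match_boxes()` matches predictions to ground truth greedily in descending
confidence order (ties by stable box id), one-to-one, per class and layer,
accepting the highest-IOU unmatched truth at or above the threshold
(default 0.5). `precision_recall()` sweeps the distinct confidences and
integrates average precision with right-running-maximum interpolated
precision — the common "area under the interpolated PR curve"; the
integration rule is a documented choice since PR "AUC" is not unique.
`count_comparison()` tallies cell centroids per class in half-open 3D
regions, warning on (but not forbidding) overlapping regions. 3D cell
benchmarking is centroid-based rather than IOU-based because the
aggregation output is a point with a diameter attribute, not a volume.

## Numerical choices and problem sizes

* Quantiles: type 7 everywhere (R default), so thresholds are reproducible
  against base R.
* Exhaustive permutation enumeration is limited to 2e5 partitions by default.
* Monte Carlo p-values use one seeded generator per call; permutations are
  drawn with `sample.int` (partial Fisher–Yates).
* Floating-point guard of 1e-12 (relative) when counting permutation
  statistics at least as large as the observed one.
* The CSV writers emit full-precision doubles and the detection reader parses
  them with base R's correctly-rounded parser, so tables round-trip
  bit-exactly.
* The test-suite works at deliberately desk-sized scales chosen to finish in
  seconds while keeping every statistical check meaningful: 4×4×4 grids for
  oracle equivalence (100 instances), 500 null datasets of 20 cubes for
  p-value calibration, 200 lattice cells for parameter recovery, and one
  ~5,600-cell regime simulation in 500³ µm³ for the end-to-end ordering and
  robustness checks.
* `run_pipeline()` funnels all randomness through a single seed and writes
  `report.json` deterministically; the resolved configuration, its hash and
  the output inventory go to `run_info.json` (CSV outputs keep their plain
  column contracts instead of carrying metadata rows).

## Known limitations

* The quartile threshold degenerates to zero for sparse classes (above); the
  cluster *count* is then dominated by isolated cells and halo percolation.
* Aggregation can split thin cells and multi-slice cells sampled
  unfavourably; recovered counts for classes near or below twice the z-step
  are biased upward, and heavily missed middle slices can split large cells.
* The permutation test conditions on the observed cluster geometry; it does
  not account for the fact that clusters were selected by the same counts
  being tested when the tested class *is* the reference class.
* Tile-overlap duplicates are resolved only implicitly by the aggregation
  distance rule; a dedicated stitching deduplication is not attempted.
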