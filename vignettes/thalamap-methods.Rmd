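---
title: "Methods: connectional domains and dendritic center-tropism in the anterior thalamus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectional domains and dendritic center-tropism in the anterior thalamus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`thalamap` re-implements, as a tested pipeline, the quantitative core of a
mesoscale connectomics-and-morphology workflow for the mouse anterior
thalamic nuclei (ATN: AD, AV, AM with its AMd/AMv divisions): detection of
connectional *domains* from grid-tabulated tracer label, normalization and
clustering of whole-brain projection profiles, and SWC-based dendritic
morphometrics including center-tropism statistics. This vignette documents
the models, the tunable parameters, the numerical choices, and the design
decisions taken where the procedure left genuine freedom. It states no
empirical result that the package's test suite and acceptance script do not
themselves compute.

# Connectional domain detection

## From segmented label to an injection x grid matrix

Segmented tracer label at one atlas level is tabulated onto square pixel
grids (`grid_spec()`, default 105 px per side at 0.6 um/px, i.e. ~63 um per
side). Anterograde (axonal) label is quantified per grid cell as the
percentage of the cell's `grid_px^2` pixels that are labeled; retrograde
label as the count of back-labeled cell bodies whose coordinates fall in
the cell. Grid indices are 0-based, row-major, origin at the image
top-left, with labels `r{row}c{col}`.

A note on the grid size: 105 px at 0.6 um/px gives a 63 um *side length*;
we treat the commonly quoted "63 um^2" figure as a side, not an area, since
only the side length is dimensionally consistent with 105 px. Both
`grid_px` and `pixel_um` are configurable.

`aggregate_matrix()` stacks the per-injection rows over the union of their
grid cells and rescales each row by its own maximum. This is the step that
makes anterograde percentages (bounded by 100) and retrograde counts
(unbounded) commensurate; per-row max scaling is our operationalization of
"anterograde and retrograde were combined", chosen because it is the
weakest transform that puts both kinds on a common [0, 1] scale without
distorting within-row structure. All-zero rows are dropped with a warning;
all-zero columns are kept in the matrix but excluded from the graph.

## Louvain communities on the bipartite graph

`detect_domains()` builds the weighted bipartite graph whose vertices are
the injections and the grid cells, with matrix entries as edge weights, and
maximizes Newman-Girvan modularity at resolution `gamma` (default 0.75)
with the multilevel (Louvain) algorithm (`igraph::cluster_louvain`), full
hierarchy, final level reported. Communities containing at least one grid
cell define domains. Two open choices were resolved as follows:

* **Graph construction.** The source procedure does not state how the
  injection x grid matrix becomes a graph. The bipartite graph is the most
  literal reading of "grouping injections with labels in common grid
  cells"; a derived grid-grid similarity graph would add a kernel choice we
  cannot justify from the text.
* **Determinism.** Louvain's result depends on vertex visitation order; we
  fix it with the `seed` argument, which is recorded in the returned
  partition and in run manifests.

Resolution below 1 favors coarser communities; the planted-block recovery
suite shows that at `gamma = 0.75` well-separated blocks (19 injections, 4
planted domains, noise SD 0.05 on the unit coverage scale) are recovered
exactly (adjusted Rand index 1.0 across 20 seeds). Community count is not
guaranteed monotone in `gamma` for Louvain; we treat monotonicity as a
diagnostic, not a contract.

`reorder_matrix()` permutes rows and columns so communities are contiguous
(values untouched), placing domains along the diagonal as in the standard
visualization; `render_domain_map()` emits the per-grid community table
from which domain maps are drawn.

# Projection-profile normalization and clustering

For each tracing case, the connectivity fraction of an ROI is
`f = count / sum(all ROI counts in the case)` and the connectivity density
is `d = (f / area) / max(f / area)`, so fractions sum to 1 and the maximum
density is exactly 1 by construction. Densities (not fractions) are the
default input to the 2D hierarchical clustering, matching their stated use
for the domain-specific displays. The linkage and distance were not
specified at the source; we default to average linkage on correlation
distance (1 - Pearson r), the common choice for profile-shape similarity,
with Euclidean/Ward available. A constant matrix (all pairwise distances
zero) falls back to input order rather than an arbitrary dendrogram.

# SWC morphometrics

`read_swc()`/`write_swc()` handle standard seven-column SWC with
`# key = value` header metadata (label, nucleus, domain). Validation
enforces unique ids, a single root, no cycles, and at least one soma node;
parse errors name the offending line. Multiple contiguous soma nodes are
permitted, with the soma position taken as their centroid (the common
convention; whether multi-point somas occur in real ATN reconstructions is
not stated anywhere we could verify).

`resample_compartments()` arc-length-interpolates every unbranched
dendritic path into directed compartments of `step_um` (default 1 um, the
stated internode scale), the last compartment of each path carrying the
remainder so branch points and tips are preserved exactly and total length
is conserved to 1e-6 relative tolerance. Remainders below 1e-6 um are
snapped onto the previous breakpoint: they are coordinate-precision noise
(SWC files are written with six decimals) and would otherwise create
degenerate compartments that distort unweighted per-compartment averages.

Feature definitions and conventions:

* **total_length** - summed Euclidean inter-node distances over dendritic
  edges (an edge is dendritic when its child node is; type codes 3 and 4
  by default, axons excluded throughout).
* **branch_count** - unbranched segments delimited by soma, bifurcations,
  and tips.
* **arbor height** - extent along the y (dorsoventral) axis over the
  dendritic nodes plus the soma; the axis is configurable, and height is
  deliberately *not* rotation invariant.
* **max_path_distance** - maximum summed edge length from soma to any tip.
* **average_branch_order** - stems leaving the soma have order 1, +1 at
  each bifurcation (a trifurcation increments once); the order of every
  ~1 um compartment is averaged, which approximates length weighting.
* **partition_asymmetry** - mean over bifurcations of
  `|n1 - n2| / (n1 + n2 - 2)` on daughter-subtree tip counts (the van Pelt
  form, the standard realization of "disproportionate distribution of tips
  between daughters"); terminal (1, 1) bifurcations contribute 0;
  k-furcations are decomposed into stacked binary splits; arbors without a
  bifurcation report `NA`.
* **sholl_profile** - crossings of concentric spheres centered on the
  soma at `shell_um` spacing (default 50 um). Shell radii are Euclidean:
  the source mixes path-distance language in prose, but concentric circles
  centered on the soma are the Sholl standard, and we follow it. Crossings
  are counted analytically per edge (roots of the segment-sphere quadratic
  in the half-open interval (0, 1], so a vertex on a sphere counts once);
  the suite checks this against a sign-change count on finely resampled
  compartments. The oracle's resolution matters: an excursion across a
  shell shorter than the resampling step is invisible to a discrete
  sign-change count, so the oracle resamples at 0.1 um, well below the
  generator's ~5 um segment scale.

# Center-tropism statistics

The *local core vector* of a compartment is the straight line from the
compartment's origin to the nucleus center; `compartment_deviation()`
returns the angle in [0, pi] between the compartment vector and this core
vector (acute = growing toward the center). Choices:

* **Center.** How the nucleus "center" was computed is never defined at
  the source; the default is the centroid of the supplied boundary
  polygon, overridable by explicit coordinates.
* **Averaging.** `average_angular_deviation()` is the unweighted mean over
  compartments ("averaged across all compartments"); because compartments
  are ~1 um this is close to length weighting, which is available via
  `weighted = TRUE`. Compartments whose origin coincides with the center
  (angle undefined) are flagged `NA` and excluded.
* **Proportion closer.** `proportion_closer_than_soma()` is the
  length-weighted fraction of compartments whose *midpoint* is nearer the
  center than the soma; midpoints avoid the bias an endpoint convention
  would give short terminal compartments.
* **2D vs 3D.** Deviations are computed in 3D by default; a `planar` mode
  drops z for section-plane analyses, since the published renderings are
  2D.
* **Edge classification.** Edge/non-edge assignment was manual in the
  original workflow. `classify_edge()` operationalizes it: a soma is
  "edge" when its distance to the boundary along the center-to-soma ray is
  at most `edge_threshold` (default 20% of the local center-to-boundary
  distance; absolute um thresholds also accepted). Somas outside the
  boundary classify as edge with a warning. The 20% default is our choice
  and is configurable; all downstream contrasts take the classification as
  data.

Angles are reported in both radians and degrees (180/pi = 57.3 deg per
radian). `deviation_vs_distance()` gives the Pearson correlation between
soma-center distance and average deviation; on cohorts built with
distance-increasing tropism it is negative (farther somas orient more
strongly toward the center). Note the published figure annotation and text
disagree slightly on this correlation (-0.63 vs -0.65); neither is an
implementation target here, only the sign and significance are asserted on
synthetic cohorts.

# Statistics and typing

* `rank_sum_test()` - two-sided Wilcoxon rank-sum; exact by complete
  enumeration of rank assignments when the combined n is at most 12 with
  no ties (two-sided p = twice the smaller tail, capped at 1), otherwise
  the normal approximation with tie and continuity corrections. The source
  says "signed rank" once and "rank sum" in its methods for the same
  independent-group comparisons; rank-sum is the statistically coherent
  choice for independent samples and is what we implement.
* `pooled_t_test()` - pooled-variance two-sample t with
  `df = n_a + n_b - 2`. Pooled (not Welch) because the printed df for the
  27-vs-45 edge contrast is 70 = 27 + 45 - 2, which only the pooled form
  produces.
* `bh_fdr()` - Benjamini-Hochberg step-up adjustment ("FDR corrections"
  with no procedure named; BH is the default in this literature). The FDR
  family grouping is explicit in the pipeline: the edge/non-edge contrasts
  form one family, the pairwise-nucleus contrasts another.
* `pearson_correlation()` - sample r with the t-transform p
  (`df = n - 2`).
* `kmeans_two_types()` - k = 2 K-means on per-column z-scored
  (total length, branch count); z-scoring is assumed because the two
  features differ by two orders of magnitude. 50 seeded restarts; Type 1
  is the more populous cluster (tie broken toward the smaller mean
  length). With exactly two rows the partition is the trivial one
  (`stats::kmeans` refuses k = n).

# The synthetic-data module

The generators exist so that every stage runs and is testable without
imaging data; they emulate the *statistical structure* the analyses
assume, not biophysics. Their defaults are the stated study conditions;
where no value is stated we fixed one realistic value and did not revisit
it.

* `generate_neuron()` grows a tree from the soma in ~5 um segments
  (uniform +-30% jitter). Each segment direction is drawn from a
  von-Mises-Fisher distribution with concentration `tropism_kappa` around
  a blend of the parent direction (weight 0.3, for path smoothness) and
  the local toward-center direction (weight 0.7). Unbranched paths run a
  geometric number of steps (mean 8) and bifurcate - at path end, or
  early with `branch_prob` per step - until `target_branches` is reached;
  the growing tip is chosen at random so tree topology is not artificially
  balanced. The directional scheme is our invention; only its controllable
  consequences are contractual: at kappa = 0 all directions are uniform
  (per-segment deviations average pi/2) and mean deviation decreases
  strictly in kappa. One measurement subtlety is documented in the tests:
  within a straight segment, sub-compartment origins are shifted along the
  segment's own direction, so 1 um sub-compartment deviations are slightly
  biased above pi/2 for arbors very close to the center; the isotropy
  contracts are therefore asserted per segment (at the center) and at the
  default 150 um soma distance (where the bias is ~0.02 rad).
* `generate_cohort()` presets mirror the study sizes. `"amd-edge-study"`:
  72 AMd neurons in a circular nucleus (radius 250 um, 72-gon boundary) -
  27 with somas at 84-97% of the radius (inside the default 20% edge
  band, so `classify_edge` reproduces 27/45 by construction) and 45 at
  15-72%. Tropism concentration follows `kappa = 8 (d/R)^2`, and edge
  neurons get smaller branch budgets (mean 38 vs 68), reproducing the
  reported directions: edge arbors smaller, edge deviation lower, and a
  negative distance-deviation correlation. The quadratic kappa rule and
  the budgets are stated-world choices, asserted only as directions.
  `"paper-cohort"`: 109 neurons - 10 AD, 17 AV, 82 AM; the AM split into
  the 72 AMd (domains 12/12/11/20/17) plus 10 AMv.
* `generate_type_mixture()` draws the 109-neuron feature table from the
  two printed components: 84 rows at length N(3645, 1428) um / branches
  N(51, 16), and 25 rows at N(8976, 1998) / N(126, 27), truncated at 0 by
  resampling. The components sit ~3 SD apart in each feature, so two-type
  K-means recovers means and sizes closely but not exactly (hard
  assignment trims each component's tail toward the other).
* `generate_grid_cases()` plants `planted_domains` contiguous grid blocks
  (default 4 over a 4 x 8 grid) and gives each of 19 injections uniform
  0.6-0.95 coverage on its block plus clipped N(0, 0.05) noise, with
  repeated injections of one ROI sharing a block, and alternating
  anterograde/retrograde rows.
* `generate_case_counts()` draws ROI counts log-normally (meanlog 4,
  sdlog 1.2: a few strong targets and a long tail) with uniform areas.

Every generator is a pure function of (config, seed): derived seeds stay
below 2^31 and equal seeds give byte-identical artifacts.

**What a green test does and does not establish.** The synthetic cohorts
reproduce sample sizes, the planted mixture parameters, and the *signs* of
the reported effects; they do not reproduce real arbor geometry (no
tortuosity model, no spines, no tissue boundaries), real label statistics
(no registration error, no segmentation artifacts), or effect magnitudes,
which are data-dependent. Directional tests on the cohorts validate the
pipeline's plumbing and the statistics' calibration, not the anatomy.

# Numerical choices and degenerate inputs

* Resampling conserves length to 1e-6 relative tolerance; sub-1e-6 um
  remainders are snapped (see above).
* Deviation cosines are clamped to [-1, 1] before `acos`.
* All-zero injection rows are dropped (warned); all-zero grid columns are
  retained in matrices, excluded from graphs, and reported as unassigned.
* A constant density table falls back to input ordering in clustering.
* Zero-variance inputs to the correlation and t tests raise structured
  errors rather than returning NaN.
* Exact rank-sum enumeration is capped at a combined n of 12
  (choose(12, 6) = 924 arrangements); beyond that the tie-corrected
  normal approximation is used, which the suite checks against the exact
  path to within 0.02 at n = 6 vs 6.

# Known limitations

* Binary masks are accepted as in-memory matrices or point CSVs; no image
  decoding is bundled (the available toolchain offers no PNG/TIFF reader),
  and no atlas registration or segmentation is attempted - the pipeline
  consumes pre-segmented input by design.
* Louvain at a fixed gamma is a point estimate; no consensus clustering
  across seeds is implemented.
* Sholl uses Euclidean shells; a path-distance variant is not provided.
* The edge rule is a geometric surrogate for expert annotation; with real
  data the annotation should be supplied, not recomputed.
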