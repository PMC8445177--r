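---
title: "Streamline clustering with orientation-invariant distances and clique merging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Streamline clustering with orientation-invariant distances and clique merging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibercliq)
```

## The problem

Whole-brain deterministic tractography reconstructs white-matter pathways
from diffusion MRI as a set of streamlines ("fibers"): 3D polylines, on the
order of $10^6$ per subject. Grouping these into spatially coherent bundles
is the entry point for bundle atlasing, visualization and
connectivity-based parcellation. Two properties make this clustering
problem unusual:

* **scale** — a million curves rules out anything quadratic in the number
  of fibers;
* **orientation ambiguity** — a streamline has no canonical direction, so
  the same anatomical fiber may be stored forwards in one case and
  backwards in another.

`fibercliq` implements a four-stage clustering pipeline built around both
constraints. Every fiber is first resampled to 21 equidistant 3D points
(the standard compact representation), and all comparisons use the
*minimum direct-flip* distance

$$
d_{ME}(a,b) \;=\; \min\bigl(d_E(a,b),\, d_E(a, b^F)\bigr),
\qquad
d_E(a,b) \;=\; \max_{i \in 1..21} \lVert a_i - b_i \rVert ,
$$

where $b^F$ is $b$ with its points reversed. $d_{ME}$ is symmetric,
non-negative and invariant to flipping either argument; it is *not* a true
metric (the triangle inequality can fail once the min kicks in), which is
why the pipeline never relies on metric-space indexing. What it does rely
on is a per-position lower bound: for any single position $j$,
$\min(\lVert a_j - b_j\rVert, \lVert a_j - b_{22-j}\rVert) \le d_{ME}(a,b)$.
The test suite exercises both facts on randomly generated fibers.

## The four stages

**Stage 1 — per-position point clustering.** The 3D points of all fibers at
positions 1, 4, 11, 18 and 21 (endpoints, middle, two intermediates) are
clustered independently with Lloyd's k-means under the plain Euclidean
point distance. The middle position uses `k_middle` clusters and the other
four `k_other`; the whole-brain operating point is 200/300 at roughly a
million fibers. Three seeding schemes are available:

* `random` — `k` distinct data points, uniformly;
* `kpp` — farthest-first (maximin) seeding: after a random first pick,
  each next centroid is the data point that maximises the minimum distance
  to all previous picks. Unlike classical $D^2$-weighted k-means++
  sampling this is deterministic after the first pick; it is implemented
  exactly as the argmax-of-$D$ recurrence and the tests compare it against
  an independent sequential transcription of that rule.
* `kpp_retract` (default) — `kpp` followed by one *retraction* of the
  initial centroids toward their mean,
  $q_i = C_i(1-r) + \bar C\, r$ with $r = 0.05$ by default. Maximin
  seeding deliberately picks extreme points and can land on outliers; a
  5% pull toward the centroid cloud blunts that without affecting
  well-placed picks. $r=0$ is a no-op and $r=1$ collapses all centroids
  onto the mean; both limits are asserted in the tests.

Numerical choices, all made for determinism: assignment ties go to the
lowest centroid index; clusters that empty out are re-seeded with the
point farthest from its current centroid; convergence is declared when no
point changes cluster (`tol = 0`) or after `max_iter = 100` iterations;
per-position runs derive their seed as `seed + position index`. When a
tractogram has fewer fibers than `k`, `k` is lowered to `N` with a
warning, which keeps small examples total.

**Stage 2 — membership grouping.** Each fiber now carries a 5-label key.
Fibers with identical keys form *preliminary clusters*. The grouping is a
stable sort by the composite key followed by a segmented reduction —
the deterministic, order-independent reading of sort-by-key /
reduce-by-key — so the output order is the lexicographic key order.

**Stage 3 — reassignment.** Preliminary clusters are split at the
"fewer than six fibers" threshold into small ($S_S$) and large ($S_L$)
sets, each with an orientation-aligned centroid (members are kept or
flipped to minimise the direct distance to the first member before
averaging; the alignment can be disabled with `align_centroids = FALSE`).
Every small cluster merges into its nearest large cluster when
$d_{ME}$ between centroids is strictly below `d_rmax` (6&nbsp;mm).
The search runs in a single pass against pre-merge large centroids, so
small clusters never chain onto one another and the result is independent
of processing order. Unmerged small clusters keep living as candidates if
they have at least 3 fibers; 1–2 fiber leftovers are discarded as noise.

The nearest-large search is accelerated by an exact pruning cascade built
on the per-position lower bound: probe the middle point first (its flip
partner is itself), then the endpoints, then positions 4/18, then the
rest, discarding any large cluster whose single-position bound already
reaches `d_rmax`. The cascade changes speed only, never semantics —
`reassign_small_bruteforce()` recomputes the same contract with all
pairwise distances, and the acceptance tests assert equality on random
150-cluster instances.

**Stage 4 — clique merging.** Candidates are grouped by the key label at
the middle position. Within each group a graph is built with an edge
wherever centroid $d_{ME} <$ `d_mmax` (6&nbsp;mm, strict), all maximal
cliques are enumerated, and cliques are processed in decreasing vertex
count, each merging its not-yet-consumed members into one final cluster.
Clique enumeration is pivoting Bron–Kerbosch with an outer loop in
degeneracy order — near-optimal for the sparse graphs this refinement
stage produces — and is verified in the tests against exhaustive subset
search (all graphs up to 12 vertices) and against igraph. Two policies the
merge order needs but no convention fixes are decided here: clique "size"
is vertex count (not fiber count), and equal-sized cliques process in
lexicographic order of their sorted vertex sets. Merged centroids are
recomputed with flip alignment.

An optional post-filter (`max_intra = 70`) removes final clusters whose
maximum member-to-centroid distance exceeds 70&nbsp;mm; at whole-brain
scale these are almost always short noisy fibers. Variant naming follows
the initialization: `CkFFC` (random), `CkpFFC` (kpp), `CeFFC`
(kpp + retraction), `CefFFC` (retraction + filter).

## Evaluation

`quality_report()` computes fiber coverage (% of fibers in final
clusters), the cluster-size, intra-distance and inter-distance
distributions, and the Davies–Bouldin index

$$
DB = \frac1n \sum_{i=1}^n \max_{j \ne i}
\frac{\alpha_i + \alpha_j}{d(c_i, c_j)},
$$

with $\alpha_i$ the mean member-to-centroid $d_{ME}$ of cluster $i$ and
$d(c_i,c_j)$ the centroid distance. Neither $\alpha$ nor the "intra
distance" has a single canonical definition; here $\alpha_i$ is the
*mean* dispersion (the conventional DB ingredient) while the 70&nbsp;mm
filter uses the *max* member-to-centroid distance (sensitive to single
stray fibers, which is what the filter is for). The max in $DB$ runs
literally over all $j \ne i$; coincident centroids raise an error naming
the pair rather than dividing by zero. On fibers degenerated to a single
repeated point, $d_{ME}$ collapses to the Euclidean 3D distance and
`davies_bouldin()` reproduces the classical point-cloud index — the tests
assert this against an independent implementation. `pop_variance()` is
the population ($\div n$) variance, used to summarise run-to-run spread
of indices; base `var()` would divide by $n-1$.

The inter-cluster distance histogram defaults to all centroid pairs; a
nearest-neighbour mode is available via `quality_report(fc, inter =
"nearest")` since conventions differ.

## The synthetic generator

`generate_tractogram()` plants ground truth at desk scale: smooth random
cubic-Bézier centerlines are rejection-sampled in a bounded box until all
pairwise centerline $d_{ME}$ reach `bundle_separation`; each bundle fiber
is its centerline plus i.i.d. Gaussian per-point offsets
(`within_spread`, in mm), resampled back to 21 points; a `flip_fraction`
subset is stored reversed; `noise_fraction` unstructured fibers carry
label −1. All randomness flows from one seed, and `labels_to_reference()`
scores a recovered clustering against the planted partition with the
adjusted Rand index (pipeline-discarded fibers count as singletons, so
discarding real fibers costs agreement; planted noise is excluded by
default or kept as its own class with `noise = "own_label"`).

What the generator does *not* emulate: anatomically realistic bundle
geometry (fanning, kissing and crossing configurations), heavy-tailed
bundle-size distributions, partial-volume noise, or the sheer fiber count
of real data. Green recovery tests therefore demonstrate the mechanics of
the pipeline — orientation invariance, conservation, determinism,
threshold semantics — not clinical-grade bundle segmentation.

## Choice of problem sizes, and a structural limitation

The test and acceptance workloads use tractograms of $10^2$–$2\times10^3$
fibers with `k` scaled down accordingly (e.g. 40/30 for the standard
20-bundle, 2,000-fiber recovery experiment); these sizes exercise every
code path in seconds while keeping all oracle comparisons exhaustive.

One property of the algorithm becomes visible at this scale. Stage 4 only
ever merges candidates that share the *same* middle-position point-cluster
label. Whenever `k_middle` exceeds the number of distinct bundle middles —
as in the scaled recovery experiment, where 40 centroids cover 20 tight
middle-point blobs — Lloyd's k-means splits blobs, the fragments of a
bundle inherit different middle labels, and no later stage can reunite
them: the recovered partition is a strict refinement of the planted one
(the final cluster count tracks `k_middle` almost exactly). At the
whole-brain operating point the relation is inverted — 200 middle
clusters for many thousands of anatomical bundle middles — so middle cells
are coarse and the failure mode does not arise. At desk scale the
practical guidance is simply `k_middle` at or below the expected bundle
count; the acceptance script reports the agreement score measured under
the scaled conditions as computed, without correcting for this effect.

## Worked example

```{r example, eval = FALSE}
sim <- generate_tractogram(synthetic_spec(
  n_bundles = 20, fibers_per_bundle = 100,
  bundle_separation = 20, within_spread = 1,
  flip_fraction = 0.3, seed = 1))

fc <- fiber_clusters(sim$tractogram, k_middle = 40, k_other = 30, seed = 1)
glance(fc)
labels_to_reference(sim$labels, fc)
autoplot(fc)
```

## Known limitations

* File I/O covers TRK, BrainVISA bundles and raw float32 dumps;
  coordinates are taken as-is (no affine/world-space handling), and the
  `space_note` tag is informational only.
* Whether centroids should be computed with or without flip alignment is
  a genuine convention choice; alignment is the default and a flag
  (`align_centroids`) disables it.
* $d_{ME}$-based merging with strict thresholds means clusterings are
  sensitive near the 6 mm boundaries; ties are broken deterministically
  (lowest index) rather than randomly.
* The implementation is single-threaded R; the stage structure
  (independent positions, independent middle groups) is
  embarrassingly parallel but no parallel backend is wired in.
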