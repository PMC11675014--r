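---
title: "Mapper shape graphs for temporal data: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapper shape graphs for temporal data: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsmapper)
```

## The method

Mapper is a topological-data-analysis algorithm that summarizes a point
cloud as a graph. For temporal neuroimaging data the point cloud is the set
of time frames of an `N x M` time-by-parcels matrix, and the output — the
*shape graph* — traces the trajectory of whole-brain activity through
recurring states without averaging across time, space, or subjects first.

`tsmapper` decomposes the algorithm into five pluggable stages:

1. **Distances.** Pairwise dissimilarities between time frames, under
   magnitude metrics (Euclidean, city-block, Chebychev), angle metrics
   (cosine, and correlation defined as 1 − Pearson r), or a *geodesic*
   metric: shortest paths on the penalized reciprocal k-NN graph (PRKNNG).
   A reciprocal edge requires mutual k-NN membership, which suppresses
   shortcut edges through outliers; if the reciprocal graph is disconnected
   it is repaired by greedily adding minimum-distance inter-component
   bridges with exponentially penalized weights.
2. **Lens.** Either an extrinsic low-dimensional embedding — classical MDS
   implemented natively, all other common algorithms behind a delegation
   registry — or the intrinsic lens, which skips dimensionality reduction
   and uses the PRKNNG with its geodesic distances directly.
3. **Binning.** Extrinsic lenses are covered by `R^d` overlapping
   rectangles parameterized by resolution `R` and gain `g`; intrinsic
   lenses by `R` geodesic balls around farthest-point-sampled landmarks.
4. **Partial clustering.** Each bin's members are clustered using
   *original-space* distances (never lens coordinates), by single linkage
   with a histogram-gap cutoff or by DBSCAN.
5. **Graph creation.** One node per cluster; an edge wherever two clusters
   share a time frame.

Downstream, a graph is *validated* by three criteria and, when label
structure is known, scored by two goodness-of-fit procedures.

## Validation and goodness of fit

A shape graph is accepted for interpretation only if

* coverage `beta` — the percentage of time points in the largest connected
  component — exceeds 70%,
* `alpha` — the percentage of nodes whose member time span exceeds the
  autocorrelation threshold `tau` = 11 s (the typical hemodynamic response
  peak) — is at least 15%, and
* the entropy `S` of pairwise inter-node distances is at least 2 bits,
  which rejects clique-like degenerate graphs.

Three details of these criteria are underdetermined and were fixed as
package choices, each recorded in the output and swappable:

* **alpha's predicate.** "Nodes describing data points over the threshold"
  is read as the node's *temporal span*, `(max index − min index) × TR`.
  Dwell time or inter-point gaps are alternative readings; the span is the
  most conservative of the three (it is the largest) and is exposed via the
  `span_fn` argument of `validate_shape_graph()`.
* **Entropy construction.** `S` uses *hop* distances between all node pairs
  of the largest connected component, unit-width integer bins, and a
  base-2 logarithm. Hop distances make the histogram binning canonical
  (distances are already integers) and keep `S` independent of the distance
  scale of the data.
* **Normalized degree scaling.** The per-time-point mean of the temporal
  connectivity matrix (TCM) row, excluding the diagonal, is min-max scaled
  to [0, 1]; a constant profile maps to zeros with a warning. The TCM
  itself is binary — two time points are similar when they share a node or
  sit in adjacent nodes — because nothing finer is consumed downstream.

For data with the four-state circular paradigm (stable-low, transition-up,
stable-high, transition-down), the **circleness** criterion checks that the
loop was captured: with nodes labeled by majority state, the graph minus
transition-down nodes must connect a stable-low node to a stable-high node
through at least one all-transition-up interior, and symmetrically for the
down arc. A direct stable-low/stable-high edge does not by itself fail the
criterion (the test is path existence); `strict = TRUE` additionally
rejects such shortcuts, off by default.

For paradigm-style data the **average delay** measures transition
extraction: changepoints of the normalized degree (exact dynamic
programming for the piecewise-constant-mean model — chosen over heuristic
detectors so that tests can compare against exhaustive search) are compared
with the expected boundary times. The mean is taken over the *expected*
times, so a missed transition inflates the delay instead of vanishing. The
pass threshold is `delta` = 12 s by default (20 s is a config value, not a
separate code path). The changepoint count defaults to the number of
interior boundaries of the paradigm — 7 for an 8-block design.

## Tunable parameters

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `k` | reciprocal neighbor count | 12 | smallest k that keeps magnitude-metric PRKNNGs well connected on the bundled generators |
| `d` | lens dimension | 2 | universal practice; bin count grows as `R^d` |
| `R` | segments per dimension / landmarks | — | swept; see the band analysis below |
| `g` | bin overlap, percent | — | swept; drives edge formation |
| `hist_bins` | linkage histogram bins | 10 | coarse enough that noise does not fake gaps |
| `eps`, `min_pts` | DBSCAN radius / core size | —, 3 | three-point minimum per cluster |
| `tau` | autocorrelation threshold (s) | 11 | hemodynamic response peak |
| `delta` | delay pass threshold (s) | 12 | separates good from failed extraction |

Numerical conventions worth knowing:

* **Extrinsic intervals.** Centers tile `[min, max]` at spacing
  `s = range/R`; widths are `s / (1 − g/100)`, which makes "overlap equals
  g% of interval width" an exact identity. Empty bins are kept so bin
  indexing is a pure function of `(R, g)`. A zero-range lens dimension
  collapses to one full-width interval with a warning.
* **Landmark bins.** Farthest-point sampling starts at index 1 by default
  and breaks ties toward the lower index; with `2*eps` the minimum
  landmark separation, the bin radius is `4*eps*g/100`. Coverage is *not*
  guaranteed at small gain; uncovered points are reported and depress
  `beta` downstream rather than being silently patched.
* **Histogram-gap cutoff.** The single-linkage dendrogram's merge heights
  are histogrammed into `hist_bins` equal-width bins over `[0, max]`, and
  the tree is cut at the first empty bin *after* the first nonempty one.
  The qualifier matters: a gap must separate observed merge heights. An
  empty bin below every height would otherwise cut at 0 and shatter each
  bin into singletons whenever the smallest merge height exceeds
  `max/hist_bins` — which is the typical situation for noisy data.
* **Ties and determinism.** k-NN ties break toward the lower index; DBSCAN
  border points join the first cluster discovered in index order; every
  generator is a pure function of its parameters and seed.
* **Bridge penalty.** The repair weight is `d * exp(d / dbar)` with `dbar`
  the mean reciprocal-edge weight: exponential in the gap size and
  scale-free through the normalization. The formula is a declared package
  choice (a hook accepts alternatives) — bridges exist to restore
  connectivity while making paths through them expensive.

## The delegation registry

Only classical MDS is implemented natively (double-centering of squared
distances, spectral decomposition, root-eigenvalue scaling; negative
eigenvalues among the top `d` produce zero-filled axes and a warning).
Twelve further embedding algorithms are registered by name with their
declared input form — pairwise distances (PCA, LDA, FactorAnalysis,
DiffusionMaps, Sammon, tSNE) or the original matrix (UMAP, Isomap, LLE,
HessianLLE, Laplacian, LTSA) — because the pipeline treats filter functions
as interchangeable and re-deriving their internals is explicitly out of
scope. Backends are attached where an established implementation is
available (`MASS::sammon`, `vegan::isomap`, `stats::prcomp`, ...); the
remaining names error at call time until the user attaches a backend with
`register_lens_backend()`. Stochastic backends require a seed, and a fixed
seed plus fixed input yields byte-identical coordinates.

## What the synthetic generators emulate

`g_schedule()` reproduces the coupled paradigm: the global coupling
parameter is held at 1.1 for 100 s, ramped to 5.0 over 200 s, held for
100 s, ramped back over 200 s, twice — 1,200 s sampled at TR 0.72 s into
1,667 frames across 8 labeled segments. `simulate_wc_bold()` integrates a
two-population (excitatory/inhibitory) rate model per region on a seeded
modular connectome, with the schedule's coupling scaling the long-range
excitatory input, and passes the excitatory activity through a canonical
double-gamma hemodynamic convolution (a balloon-type transform can be
plugged in). Its parameter defaults are the package's own choice of a
well-behaved operating point, not an estimate of any published model — the
published biophysical parameterization lives in work this package does not
reimplement — so analyses never depend on its exact trajectories, only on
its interface and label structure.

`synth_circular_bold()` is the workhorse: a phenomenological generator
whose noiseless trajectory is a genuine closed loop (the two transition
arcs are offset in opposite directions along a third orthogonal pattern),
with the same label structure as the simulated paradigm. Two defaults
define its regime:

* `noise_sd = 0.1`, an implied per-feature SNR near 2.3 — inside the range
  over which fMRI-like degradation is normally studied;
* `jump_steepness = 8`, a sigmoidal time-warp of the transition arcs: the
  trajectory lingers near the attractor it leaves, crosses the middle of
  the arc quickly, and settles into the destination, as a driven bistable
  system does. This warp is what produces the characteristic
  high-resolution/low-gain failure (the sparse mid-arc samples disconnect
  the graph); constant-speed interpolation has no such discontinuity and
  would make that failure mode unobservable.

The warp has one deliberate consequence: transition-*labeled* samples
mostly sit near the stable patterns, so degree-profile changepoints lag
the label boundaries by a roughly constant offset. Analyses that score
extraction against label boundaries (the average-delay GOF and the
shuffled-null comparison) therefore use `jump_steepness = 0`, where the
dynamics align with the labels; the topology analyses (circleness, the
resolution-gain band) use the warped default. Both choices are visible in
the calling code.

What these generators do *not* emulate: spatial correlation structure of
real parcellations, physiological confounds (motion, drift beyond the
injected noise model), inter-subject variability, and the rich multi-task
structure of real paradigms. Passing tests on them demonstrates that the
algorithmic machinery recovers known topology and timing under controlled
degradation — not that any particular parameter set is right for a given
real dataset.

Degradation utilities follow the stated worked rules: `add_noise()` scales
an equal-variance mix of drift, AR(1) and white components so that the
noise standard deviation is `signal sd / SNR` per feature ("amplitude" is
read as the per-feature standard deviation, so SNR 0.5 means noise at
twice the signal sd); `smooth_downsample()` applies a 4-sample boxcar
before decimation (TR 0.72 s at factor 3 becomes 2.16 s over 556 of 1,667
frames); `shuffle_blocks()` permutes 7-frame blocks with a seed-shared
permutation, preserving within-block autocorrelation while destroying
global order.

## The resolution-gain band

On the circular generator at its defaults, the reference configuration
(geodesic Euclidean distances with k = 12, CMDS lens, R = 20, g = 70%,
linkage clustering) passes validation and circleness, while the two
extremes fail in the two documented styles: R = 40, g = 50% fragments
(coverage beta drops to ~48%) and R = 10, g = 90% degenerates into a
near-clique (entropy ~0.2 bits). The suite asserts exactly this
band-with-failing-corners structure; `aggregate_stats()` +
`pass_count_matrix()` reproduce the full sweep for any grid.

## Problem sizes used by the tests

The suite and the acceptance script run at the generators' native sizes
where the quantity depends on them (1,667-frame schedules for the
schedule arithmetic and the band analysis; 10,000-sample series for SNR
ratios) and at reduced sizes where only the property matters: oracle
comparisons use 6-30-point instances (100 each), and the shuffled-null
comparison uses a 600-s schedule (834 frames) over 10 seeds, the same
construction at half duration.

## Known limitations

* Dense `N x N` distance matrices throughout; the intended regime is
  `N` up to a few thousand time frames.
* Extrinsic covers are axis-aligned rectangles in up to 3 lens dimensions;
  non-rectangular polytopes and adaptive covers are out of scope, as are
  the adjacent-bin-only edge variant and the directed temporal variant.
* The correlation distance deliberately violates the triangle inequality
  (its square root would not); geodesic construction on top of it is
  allowed but the path metric then lives on a non-metric base.
* `alpha`, `S`, and the changepoint count rest on the documented package
  choices above; alternative operationalizations plug in through the
  exposed hooks rather than code edits.
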