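---
title: "Participation coefficients for temporal networks: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Participation coefficients for temporal networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(temporalpc)
```

## The measurement problem

A temporal network is a sequence of weighted connectivity snapshots
$W^{(1)}, \dots, W^{(T)}$ over the same $N$ nodes — in functional
neuroimaging, per-time-point connectivity among parcels. The participation
coefficient (PC) of node $i$ against a community partition with
communities $s$ is

$$P_i = 1 - \sum_s \left(\frac{k_{is}}{k_i}\right)^2,$$

where $k_{is}$ is $i$'s strength (sum of edge weights) into community $s$
and $k_i$ its total strength. $P_i = 0$ when all strength stays within one
community; it approaches $1 - 1/S$ when spread evenly over $S$
communities. In network neuroscience a high PC is read as *integration*, a
low PC as *segregation*.

Applied through time there are four distinct estimators, all provided
here:

* **static PC** (`static_pc`): one snapshot, one partition;
* **PC\_S** (`pc_s`): $P_{it}$ per slice against a single static
  partition — every value shares the same community context, so the time
  series is internally comparable;
* **PC\_T** (`pc_t`): $P_{it}$ per slice against that slice's own
  temporal partition. Each value is correct in isolation, but consecutive
  values are computed against *different* community contexts. A node whose
  community splits because edges weakened gains PC\_T (its remaining edges
  now cross a boundary), which reads as "more integration" exactly when
  connectivity declined. The toy scenarios `make_toy("fig2_split")` and
  `make_toy("fig2_extend")` construct the two directions of this
  inversion, and the test suite verifies the sign pattern;
* **TPC** (`tpc`): for each slice $t$, the PC is evaluated against the
  partition of *every* time point $u$ and averaged,
  $$P_{it} = 1 - \frac{1}{T} \sum_{u=1}^{T} \sum_{s \in \mathcal{P}_u}
    \left(\frac{k_{its}(u)}{k_{it}}\right)^2 .$$
  Every slice is scored against the same set of community contexts, so
  values are again comparable across time while the temporal community
  information is retained.

TPC deliberately sums over all $T$ partitions *including repeats* (the
$1/T$ normalization), rather than over unique partitions: a community
configuration that recurs often contributes proportionally to every
estimate. This weighting is part of the definition, and a dedicated test
distinguishes it from the deduplicated alternative.

TPC rests on a *recurrence assumption*: community configurations can
recur, so scoring a snapshot against another time point's partition is
meaningful. For systems with irreversible dynamics (e.g. contagion
networks, where post-outbreak communities cannot precede the outbreak) the
averaging is not appropriate, and `pc_s` is the prudent choice.

## Pipeline and estimation choices

The standard order of operations (`run_pipeline()`) is: estimate
time-varying connectivity → zero out negative edges → detect communities
(static and per slice) → consensus-relabel → measures → divergence report.

**Time-varying connectivity.** The default estimator
(`estimate_tvc_weighted_pearson`) computes, per time point $t$, a weighted
Pearson correlation in which other time points are weighted by spatial
similarity: Euclidean distances from $t$ to every time point are min–max
scaled per row to $[0,1]$ and the weight is one minus the scaled distance,
so $t$ itself gets weight 1 and the farthest time point weight 0. The
order of transformation matters because $1-d$ on raw, unbounded distances
can be negative; scaling first keeps weights in $[0,1]$ while preserving
the intent that spatially nearby time points support the estimate.
Weighted moments use the frequency-weight convention (denominator
$\sum_t w_t$), making results reproducible bit for bit; with uniform
weights the estimator reduces exactly to the ordinary Pearson correlation
(tested at $10^{-12}$).

The alternative estimator (`estimate_tvc_mtd`) multiplies the temporal
derivatives of each pair of series, normalizes by the derivative
root-mean-square of each node (so a node's self-coupling averages exactly
one over the series — the uncentered normalization makes that identity
exact), and smooths with a truncated moving average over
`half_window = 4` points each side. It yields $T-1$ slices; window
truncation at the boundaries keeps the output length deterministic.

Negative edges are removed by `threshold_negative_edges` *after*
estimation and *before* community detection and participation, never
inside the estimators; signed-network generalizations of PC are out of
scope.

**Communities.** Modularity maximization (Louvain, via igraph) with
resolution parameter 1 by default, run on the thresholded static
correlation matrix for the static partition and independently per slice
for temporal partitions. Seeds are mandatory and per-slice seeds are
derived deterministically from the stage seed. An all-zero slice gets
singleton communities with a warning.

**Temporal consensus.** Slice-wise Louvain labels are arbitrary, so
`temporal_consensus` relabels them: sweeping forward, each community at
$t$ is matched one-to-one to the community at the already-relabeled $t-1$
with the smallest Jaccard distance between node sets, greedily in
ascending distance. A match requires at least one shared node (distance
$< 1$); unmatched communities receive fresh, never-reused labels. Ties are
broken by the smallest member node index, then the smallest candidate
label, making the result independent of the incoming label alphabet. The
forward sweep (labels inherited from the past) was chosen over the
backward equivalent because it yields stable labels from the first slice
onward. Consensus only relabels — per-slice partition structure is
preserved exactly and the operation is idempotent (both are tested
properties). `flexibility` (fraction of consecutive steps at which a
node's label changes) requires consensus labels and warns otherwise.

**Numerical conventions.**

* A node with zero strength at a slice has undefined $k_{its}/k_{it}$;
  all PC variants assign 0 ("no participation").
* "Degree" is weighted strength throughout; the networks are weighted.
* The within-module degree z-score (`module_degree_zscore`) uses the
  population (N-denominator) standard deviation; singleton and
  zero-variance communities give $z = 0$. `z_S` pairs with `pc_s` (static
  partition at every slice) and `z_T` with `pc_t`.
* Hub-overlap selections (`hub_overlap`) take exactly
  $\lceil p\% \cdot \text{count} \rceil$ points, breaking value ties by
  earliest time then lowest node index, so selections are deterministic.
* Quadrant analysis (`quadrant_analysis`) classifies $(node, time)$
  points by the signs of $PC_T - PC_S$ and $z_T - z_S$; points exactly on
  an axis are excluded from the discordant count and reported separately.
* The heteroscedasticity diagnostic bins one measure by deciles of the
  other (the bin count is configurable, shrinking automatically if a
  quantile bin would hold fewer than two points) and applies Bartlett's
  test; the grouping of continuous values into bins is a package choice,
  not part of the test's definition.

## The synthetic generator

`generate_recurring_timeseries` realizes the recurrence assumption
directly: time is tiled by epochs; each epoch draws from a zero-mean
multivariate normal whose correlation matrix has the block structure of
that epoch's *state* (within-block correlation 0.6, between-block 0.05 by
default), states cycle so each recurs at least twice, and independent
Gaussian measurement noise (sd 0.2) is added. The defaults — 40 nodes,
200 time points, two states of four 10-node blocks with the second state
a 5-node rotation of the first, epochs of 50 — give overlapping but
genuinely different community configurations, so static and temporal
contexts diverge. A piecewise-stationary design was preferred over a
continuously drifting covariance because it plants exact, recoverable
partitions and recurrences.

What the generator does *not* emulate: hemodynamics, temporal
autocorrelation, global signals, subject variability, and — importantly —
state-specific activation topographies. The last point has a measurable
consequence: because same-state epochs are independent draws from the same
distribution, time points of the same state are no closer in Euclidean
space than time points of different states, so the distance-based weights
of the default estimator cannot concentrate on same-state time points and
every slice estimate mixes both states. Per-slice community detection on
these mixtures recovers the active state's blocks only partially (well
above chance; tested), whereas the same detector recovers them *exactly*
when the weighted correlation is restricted to same-state time points
(also tested). Passing tests therefore demonstrate correctness of the
measures, consensus and diagnostics, and qualitative behavior of the
estimator — not that per-slice partitions on real data are exact.

The two-slice toys (`make_toy`) isolate single mechanisms: edges
spreading across communities (`fig1b`), absorption into a strengthened
community (`fig1c`), partition change without any change in the focal
node's own edges (`fig1d`), community split/extension driven by edge
decreases/increases (`fig2_split`, `fig2_extend`), and the single-edge
merge/split scenario (`fig3`). Edge weights use two base levels (1.0
strong, 0.5 weak); in `fig2_*` additional inter-block support edges away
from the focal node make the planted merge also the modularity-optimal
partition, without affecting any focal-node value. Only the *signs* of
the focal node's changes are asserted. For `fig3`, random weight
configurations are drawn from ranges chosen so that the construction is
honored (the bridge is large enough to merge and small enough to split):
within edges 0.8–1.2, merged bridge 0.8–1.6, split bridge 0.05–0.3,
cross-community edge 0.2–0.5; over these ranges the TPC of the focal node
at the merged slice provably dominates the split slice.

## Problem sizes

The test suite exercises the TPC oracle equivalence on 200 random
instances (up to 20 nodes, 10 slices), consensus and invariance
properties on ~100 random instances each, and the full synthetic study on
20 generator seeds at the default 40 × 200 size; the acceptance script
reruns the same study end to end. These sizes were chosen so the entire
suite completes in about a minute on a laptop while every property is
exercised at nontrivial scale.

## Known limitations

* Undirected, nonnegative-weight networks only; directed and signed
  variants are rejected rather than approximated.
* The consensus matcher is greedy; a globally optimal assignment
  (e.g. Hungarian) could differ on adversarial ties, though not on the
  structures modularity detection produces in practice.
* TPC inherits the recurrence assumption; for non-recurrent systems the
  averaged contexts are not meaningful.
* The uniform-scaling invariance of PC holds per node-slice; the stronger
  claim that *any* decrease of all of a node's edge weights can never
  raise its TPC is asserted only for uniform scalings and the merge/split
  construction, where it is tested.
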