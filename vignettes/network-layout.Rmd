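---
title: "Drawing rooted phylogenetic networks: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drawing rooted phylogenetic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phynetdraw)
```

## The model

A rooted phylogenetic network on a taxon set X is a directed acyclic graph
N = (V, E, ρ, λ) with exactly one in-degree-0 node (the root ρ), a bijection
λ between X and the out-degree-0 nodes (the leaves), no *through nodes*
(in-degree 1 and out-degree 1), and leaves of in-degree at most 1. A node of
in-degree ≥ 2 is *reticulate*; an edge is classified by its target. Two
biological readings of a reticulation are supported: a *combining* event
(hybridization: all in-edges equivalent) and a *transfer* event (HGT:
exactly one in-edge, the transfer-acceptor, is the continuing lineage; the
others carry transferred material). `validate_network()` checks all of these
rules and reports violations as data rather than raising conditions, because
partially captured or hand-edited networks are expected inputs.

## Backbone-tree layout

All y-coordinates are computed on a spanning *backbone tree* B. In the
combining view, every reticulate node v loses its in-edges and is re-attached
below its *lowest stable ancestor* LSA(v), the last node on every ρ→v path.
LSA(v) is exactly the immediate dominator of v, which is how the package
computes it (via igraph's dominator tree; a path-enumeration oracle
cross-checks this in the tests). In the transfer view, a flagged reticulate
node keeps only its acceptor edge; unflagged nodes fall back to combining
treatment. Rerouting can orphan a parent whose only children were reticulate;
such nodes become *unlabeled leaves* of B and are handled explicitly
throughout.

A post-order traversal of B under its per-node child order O gives the i-th
leaf visited y = i (0-based; this matches the equal-spacing rule and the
circular angle formula, whose y range is 0..n−1); an internal node receives
the mean of its children's y (default) or of its descendant leaves' y.
Cladogram x-coordinates are depths d(v) — the maximum edge count on any
root path; phylogram x-coordinates accumulate edge weights (below). Each
main edge (tree or acceptor) is drawn as the two-segment right-angled path
(x(v), y(v)) → (x(v), y(w)) → (x(w), y(w)); with distinct leaf rows and
strictly increasing x along main edges, these paths cannot cross — the
property the test suite verifies with an exact axis-aligned
segment-intersection check (`count_edge_crossings()`).

The *late* variant right-aligns all leaves at the maximal depth and then
assigns every internal node min over children minus 1, in reverse
topological order. The early/late distinction is defined for cladograms
only; a late phylogram is rejected since weighted x-coordinates are not free
to move. Early/late pushes all non-leaf nodes uniformly, including
reticulate ones.

## Transfer depths

In the transfer cladogram, a transfer edge (v, w) reads best when drawn
horizontally, so whenever d(v) < d(w) the source is raised to d(w), after
which consistency along tree/acceptor edges (d(child) ≥ d(parent) + 1) is
restored; the two steps repeat to a fixed point, capped at |V| + 2 passes.
One subtlety deserves recording: the combined constraint system has *no*
finite fixed point when a transfer source is a backbone ancestor of its own
target (the constraints then form a positive cycle). Such configurations are
exactly the time-*in*consistent ones — a lineage transferring material into
its own descendants — and cannot occur in networks where every transfer
connects lineages alive at a common time. On time-inconsistent input the
function stops at the pass cap, warns, and returns the best-effort map
rather than erroring, since such networks are otherwise perfectly drawable.

## Phylograms

Every tree and transfer-acceptor edge must carry a non-negative weight ω;
processing nodes parents-first, a tree/transfer node gets
x(v) = x(u) + ω(e) from its unique main in-edge, and a combining node gets
max over parents plus δ, which keeps reticulate edges running strictly
left-to-right. δ defaults to 2% of the maximal root-to-node main-path
distance (floor 1e−6): large enough to be visible, small enough not to
distort branch lengths. The additive contract x(w) − x(v) = ω(e) is exact in
floating point whenever the weights (and δ) are dyadic rationals, which is
how the acceptance checks exercise it; for arbitrary doubles it holds to
rounding error.

## Displacement optimization

The quality objective is the *reticulate displacement*
RD = Σ |y(v) − y(w)| over the displacement edge set R. R contains the
reticulate edges, minus transfer-acceptor edges (they are drawn as main
lineage), minus any original edge that coincides with the backbone edge into
its target. The last exclusion matters in two places: when LSA(v) happens to
be one of v's parents, the rerouted backbone edge duplicates an original
edge, which is then drawn as the node's main attachment; and in the MinLA
reduction (`minla_to_network()`), where the star edges from the root are
backbone by construction and counting them would add an order-dependent term
that breaks the equivalence between RD and the linear-arrangement cost
Σ |f(u) − f(v)|. With the exclusion, the reduction is exact in both
directions, which the tests verify against brute-force enumeration over all
n! arrangements and an independent subset-DP oracle.

Minimizing RD over child orders is NP-hard (it contains MinLA), so the
optimizer is a structured local search:

1. **Single-node sweeps.** Every branching node of B is visited in
   pre-order. At each node, all child permutations are tried when there are
   at most eight children (the exhaustive threshold, configurable);
   otherwise simulated annealing over random pairwise swaps is used, with
   Metropolis acceptance exp(−Δ/T) and the schedule: start temperature 1000,
   end temperature 0.01, 1000 iterations per temperature step, cooling rate
   0.95. Candidate costs are always evaluated *globally* (full y
   recomputation through a compiled kernel), never from stale local
   coordinates. Sweeps repeat until no strict improvement.
2. **Pairwise refinement.** Single-node moves cannot realize a simultaneous
   reorder of two nodes, and such couplings do occur: coordinate descent
   alone stalls above the global optimum on a few percent of small random
   networks. After the sweeps converge, pairs of small nodes are jointly
   re-optimized by exhaustive product search (budget-capped); any
   improvement loops back to step 1.

Two design points are deliberate deviations from the narrowest reading of
the per-node pre-order heuristic. First, the visited set is *all* branching
nodes, not only the LSA anchors of the reticulations: under children-mean
averaging, reordering any node shifts the y of its ancestors (block offsets
do not cancel in the mean), so restricting to LSA nodes demonstrably misses
optima. Second, the pass is repeated to convergence plus pairwise
refinement rather than run once; with both in place the optimizer matched a
full joint-enumeration oracle on 500/500 small random networks (≤ 7
backbone leaves, ≤ 3 reticulations) across five independent replicate
streams, while remaining a heuristic at scale. The optimizer never returns
an order worse than its input; ties keep the incumbent, making results
deterministic for a fixed seed (a single seeded RNG per call drives all
annealing).

The public `simulated_annealing_order()` runs the same schedule in pure R
against an arbitrary cost function; `optimize_child_orders()` routes the
displacement objective through the compiled kernel, and the tests pin the
two cost evaluations against each other.

## Circular layouts and equal spacing

A circular drawing maps y to the angle y / H × 360°, with H = number of
backbone leaves + 1, and radius x + r0 (r0 = 1 drawing unit by default so
the root is not a degenerate center point). The optimizer's circular cost is
min(|Δy|, H − |Δy|), never exceeding H/2 and agreeing with the linear cost
for gaps up to H/2.

Because B may contain unlabeled leaves, raw post-order y can leave uneven
gaps between taxa. `equalize_leaf_spacing()` re-runs the traversal after
optimization: labeled leaves get the integers 0..|X|−1 in traversal order; a
run of m unlabeled leaves between labeled neighbors at k and k+1 gets
k + j/(m+1); leading/trailing runs extend outward by the same fractional
steps. The relative leaf order — the optimizer's output — is preserved
exactly.

## The random network generator

`random_network(n, h)` grows a binary tree on n leaves by uniform edge
attachment, assigns node times strictly increasing from the root, and adds
each of the h reticulations by sampling a time point, choosing two distinct
tree edges alive at that time, subdividing both there, and connecting the
new nodes with a reticulate edge; tree edges carry their time spans as
weights, and `acceptors = TRUE` flags each reticulation's original lineage
as its acceptor edge. The construction guarantees validity, acyclicity and
global time consistency — transfers connect contemporaneous lineages, as in
standard HGT network simulators, which also makes the transfer-depth
constraint system solvable (see above). Default h = round(0.2 n) mirrors
the reticulation density used in the layout benchmark. What the generator
does *not* emulate: non-binary divergences, reticulations between
non-contemporaneous lineages, rate heterogeneity in branch lengths
(uniform(0.3, 1.2) per edge), or any inference-induced correlation between
topology and reticulation placement found in real published networks. Tests
passing on these networks therefore speak to algorithmic correctness, not
to performance on any particular empirical network class.

## Image capture

The capture pipeline assumes a phylogeny drawn in dark, thin lines on a
white background with small nodes. Binarization thresholds luminance (Otsu
by default). Skeletonization is Zhang–Suen thinning (8-connected
foreground, 4-connected background), written in-package since no installed
R package provides morphological thinning. Node detection uses the
8-neighbor count on the unit-width skeleton — 1 neighbor means endpoint,
≥ 3 means junction — with 8-adjacent junction pixels merged into centroid
clusters; the count rule was chosen and validated on constructed fixtures,
as the exact mask is otherwise a free design choice. Path tracing walks
degree-2 pixel chains between clusters; dead-end walks of artifact pixels at
sharp corners are dropped as strays, and node-free closed curves are kept as
loops. Paths entirely inside a label bounding box are removed.

Assembly creates the root at the indicated location, splitting a path
interior if needed, infers the drawing orientation by comparing the root
location with the node bounding box (radial when the root sits in the
central quarter), and then incorporates paths as edges in order of
increasing distance from the connected component, breaking distance ties by
when each path's connected endpoint joined (so the component grows
breadth-first from the root — without this, an edge can be oriented from a
later-attached node and invert part of the topology). A path with one
connected endpoint is oriented away from it. A path with *both* endpoints
already connected is oriented along the drawing direction; it is left in
`unresolved_paths` when that direction is ambiguous (equal projections),
when the oriented edge would create a directed cycle, or when it returns to
a single node — a closed triangle with the root on one corner, for example,
yields exactly one unresolved path. Unresolved paths are data for the user,
not errors: real figure captures routinely need manual post-editing, which
is what `remove_through_nodes()`, `replace_with_crossing()` (pairing
in/out edges by direction collinearity, ties by edge order) and
`merge_nodes()` (refusing to merge two taxa or to give the root an
in-edge) are for. OCR is deliberately a sidecar interface — a table of
label boxes and texts — keeping the pipeline deterministic and free of an
OCR engine dependency; labels attach to the nearest captured leaves.

## Numerical and testing choices

Strict-improvement thresholds of 1e−9 guard all optimizer comparisons
against float noise; serialization writes weights with 17 significant
digits so doubles round-trip exactly; isomorphism checking is VF2 with
vertex colors for taxa/root and edge colors for acceptor flags (and
optionally weights). Test problem sizes were chosen to keep the full suite
fast while exercising every branch: round trips at n ≤ 30 with up to 6
reticulations, optimizer-versus-oracle at ≤ 7 backbone leaves (where joint
enumeration is exact), annealing quality on 9–10-vertex MinLA stars (the
smallest sizes that force the SA branch) against a subset-DP optimum, the
displacement benchmark at n = 50 with h = 10 over 10 replicates, and
capture round trips on 50 rendered trees with n ≤ 20.

## Known limitations

The backbone-tree abstraction itself can hide improvements that would
require moving subtrees between different backbone parents; the optimizer
explores child orders only. The transfer-depth adjustment is best-effort on
time-inconsistent networks. The capture pipeline does not handle labels or
annotation lines overlapping the phylogeny, color-coded semantics, or
vector/PDF input, and reticulate edges that cross other edges in the source
figure generally need manual resolution of the resulting
degree-2/degree-2 crossing nodes. Rendering aims at structural fidelity,
not typography.
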