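# phynetdraw

Layout, optimization and image capture of rooted phylogenetic networks.

Rooted phylogenetic networks generalize rooted trees to evolutionary
scenarios with reticulate events — hybridization, horizontal gene transfer,
reassortment. A network N = (V, E, ρ, λ) is a DAG with a single root ρ and a
bijection λ between the taxon set and the leaves; nodes of in-degree ≥ 2 are
*reticulate*. Unlike trees, such networks are generally non-planar, and a
good drawing has to manage the crossings that reticulate edges cause.

`phynetdraw` is aimed at people who need publication-style drawings of such
networks (or need to get a network *out of* a published figure): it
implements

* a **backbone-tree layout**: every reticulate node is re-attached below
  its lowest stable ancestor (LSA — the last node on all root paths,
  equivalently its immediate dominator), giving a spanning tree B whose
  post-order traversal assigns y-coordinates; x-coordinates come from depths
  (cladogram) or edge weights (phylogram). Tree edges are drawn as
  right-angled two-segment paths and never cross; reticulate edges are
  drawn as curves and may cross.
* **two interpretations of reticulations**: the *combining* view
  (hybridization — all in-edges drawn alike) and the *transfer* view (HGT —
  the designated transfer-acceptor edge, `##` in extended Newick, is drawn
  as the main lineage, and transfer sources are pushed to the depth of
  their targets so transfers run horizontally).
* **reticulate-displacement optimization**: the quality score is
  RD = Σ over reticulate edges (v,w) of |y(v) − y(w)| (excluding
  transfer-acceptor edges), minimized over the child orders of B. Each
  branching node is searched exhaustively (≤ 8 children) or by simulated
  annealing (start temperature 1000, end 0.01, 1000 iterations per step,
  cooling rate 0.95), followed by an exact pairwise refinement. Minimizing
  RD is NP-hard — it contains the Minimum Linear Arrangement problem, a
  reduction the package exposes as `minla_to_network()` and uses as a test
  oracle.
* **early/late, linear/circular variants**, equalized leaf spacing (labeled
  leaves at 0, 1, …, |X|−1 with unlabeled backbone leaves interpolated
  fractionally), and a circular cost min(|Δy|, H − |Δy|) with H = number of
  backbone leaves + 1.
* an **image-capture pipeline**: binarize → Zhang–Suen skeletonization →
  junction/endpoint detection by pixel mask → path tracing → label-box
  filtering → rooted assembly with cycle rejection, plus the clean-up
  operations (through-node removal, crossing replacement, node merging).
  OCR is not bundled: label text comes from a sidecar table (e.g. from an
  external OCR step, or from `render_raster_fixture()` in tests).
* extended Newick I/O (`#H1`/`#LGT1`/`#R1`/`#1` tags, `##` acceptor
  notation, edge lengths), a time-consistent random network simulator, and
  SVG/raster renderers.

## Worked example

```r
library(phynetdraw)

net <- parse_extended_newick("(((a,(x)#H1),((y)#H2,b)),((#H1,c),(d,(#H2,e))));")[[1]]
net
#> Rooted phylogenetic network: 17 nodes, 18 edges, 7 taxa, 2 reticulations
#> Taxa: a, x, y, b, c, d, e
#> Valid network.

layout_network(net, optimize = FALSE)
#> Network layout: combining cladogram (early), 17 nodes
#> Reticulate displacement: 15

lay <- layout_network(net, sa = sa_config(seed = 1))
lay
#> Network layout: combining cladogram (early), 17 nodes
#> Reticulate displacement: 8
```

The displacement drops from 15 to 8: the optimizer found child orders that
pull the two reticulations' parents vertically closer, so the curved
reticulate edges span fewer leaf rows. `plot(lay)` draws the result;
`render_svg(lay, "net.svg")` writes it as SVG. At benchmark scale:

```r
sim <- random_network(50, 10, seed = 42)        # 50 taxa, 10 reticulations
b0  <- build_backbone(sim, "combining")
reticulate_displacement(assign_y(b0), rd_edge_set(sim, b0))
#> [1] 208.4013
optimize_child_orders(sim, b0, sa = sa_config(seed = 1))$displacement
#> [1] 102.5241
```

Capturing a topology from a raster figure:

```r
lay <- layout_network(random_network(8, 1, seed = 6), sa = sa_config(seed = 1))
fx  <- render_raster_fixture(lay)               # black-on-white pixel matrix
cap <- capture_network(fx$raster, fx$root, labels = fx$labels)
network_isomorphic(remove_through_nodes(cap$network), lay$net)
#> [1] TRUE
```

A command-line wrapper for the same operations (`layout`, `convert`,
`simulate`, `render`, `capture`) is installed at
`inst/scripts/phynetdraw.R`.

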