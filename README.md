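# netgrid

Grid layouts for biochemical networks: compact, module-separated 2D
drawings of metabolite–reaction graphs, computed by combinatorial
optimization on an integer lattice.

## The problem and the method

Force-directed layouts of metabolic networks tend to smear functionally
related reactions across the canvas. `netgrid` instead places every node on
an integer grid, one node per cell, and minimizes the interaction energy

```
cost(R) = Σ_{i<j} w_ij · d_ij(R)
```

where `d_ij` is the Manhattan distance between the cells of nodes *i* and
*j*, and the integer weight `w_ij = χ(L_ij)` is a step function of the
unweighted graph distance `L_ij`. Positive weights attract (short-range
pairs are pulled together), negative weights repel (distant or unreachable
pairs are pushed apart). Three built-in χ tables — the **common**,
**compact** and **stretched** layout styles — trade attraction off against
repulsion; adding a positive boost to `w_ij` for node pairs in the same
functional module makes modules aggregate into visually coherent blocks.

The optimizer is a *neighborhood test* — sweep the nodes, moving each to
the best strictly-improving vacant cell among its 8 neighbors, until no
single-node move helps — wrapped in *re-optimization-after-perturbation*
restarts: each of `niter` iterations displaces every node with probability
`p` to a random adjacent vacant cell, re-optimizes locally, and accepts the
candidate only if the cost strictly drops. Defaults are `p = 0.7` and
`niter = 60`. The inner loop is C++ (via Rcpp) with O(n) incremental cost
updates, so genome-scale subnetworks (hundreds of nodes) lay out in about a
second.

The package also ships the supporting plumbing: edge-list / SIF-style I/O,
bipartite construction from reaction tables, a currency-metabolite
stoplist, a planted-partition generator of modular test networks with known
ground truth, deterministic SVG rendering with per-module shapes and
colors, and a command-line interface (`inst/cli/netgrid`).

## Worked example

```r
library(netgrid)

net <- fixture_network(290)          # 3-module metabolite-reaction network
net
#> netgrid network: 290 nodes, 459 edges
#>   classes: metabolite=146, reaction=144
#>   modules: central_metabolism=100, lipid_synthesis=95, nucleotide_synthesis=95

fit <- netgrid(net, style = "common", seed = 1,
               boost = list(delta = 10, distances = c(2, 3)))
summary(fit)
#> netgrid fit: 290 nodes, 35 x 35 grid, style = common
#>   cost: -719,333 (from initial local minimum -191,456; 42/60 restarts accepted)
#>   occupied bounding box: 35 x 35 (area 1225)
#>   mean intra-module Manhattan distance:
#>     central_metabolism           12.57
#>     lipid_synthesis              17.18
#>     nucleotide_synthesis         10.50
```

The final cost is the minimized interaction energy (exact integer
arithmetic; more negative is better — here the accepted restarts improved
the initial local minimum by a factor of almost four). The intra-module
distances show the effect of the `delta = 10` boost applied to same-module
pairs at graph distances 2–3: without it the module means sit around 27 on
this grid, i.e. members are scattered; with it each module contracts into a
tight block. `render_svg(fit, file = "map.svg")` draws the result;
`coef(fit)` returns the integer coordinates.

From the shell:

```sh
inst/cli/netgrid synth --sizes 100,95,95 --p-in 0.07 --p-out 0.002 --bipartite --seed 7 --out-prefix toy
inst/cli/netgrid layout --classes toy.classes.tsv --seed 1 --svg toy.svg toy.edges.tsv
```

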