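---
title: "Grid layout of biochemical networks: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid layout of biochemical networks: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netgrid)
```

## The model

A layout is a placement `R = (r_1, ..., r_n)` of the `n` network nodes on
an integer grid, one node per cell. Its quality is the total pairwise
interaction energy

$$\mathrm{cost}(R) \;=\; \sum_{i<j} w_{ij}\, d_{ij}(R),$$

with `d_ij` the Manhattan distance between the two occupied cells and
`w_ij` an integer interaction weight; lower cost is better. The sum runs
over unordered pairs of distinct nodes — summing ordered pairs would only
double every term, and self-terms are meaningless because the one-node-
per-cell invariant keeps all pairwise distances positive.

Weights come from the graph structure: `w_ij = χ(L_ij)` where `L_ij` is
the unweighted shortest-path distance and χ is a non-increasing integer
step function. Nodes at graph distance 1 attract strongly, mid-range pairs
attract weakly, and remote pairs repel, so densely interconnected regions
condense while unrelated regions separate. Treating the network as
undirected and unweighted is deliberate: both the cost and the graph
distance are symmetric, so reaction directionality carries no information
the optimizer could use.

### Layout styles

The three built-in χ tables are design points on the attraction–repulsion
trade-off, chosen so that each satisfies a qualitative contract; the
integers themselves are configurable (`layout_style()`, `read_style()`):

| distance | common | compact | stretched |
|---------:|-------:|--------:|----------:|
| 1        | 9      | 9       | 6         |
| 2        | 4      | 4       | 1         |
| 3        | 1      | 2       | −2        |
| 4        | −1     | 1       | −2        |
| ≥ 5      | −1     | 0       | −2        |
| unreachable | −1  | 0       | −2        |

*common* roughly balances attraction and repulsion, spreading nodes evenly
while keeping modules distinct; *compact* is attraction-dominated
(no entry is negative), so the drawing condenses into the smallest area;
*stretched* attracts only at short range, pushing modules far apart. The
validation battery checks the behavioral ordering these tables must induce
— mean occupied bounding-box area compact ≤ common ≤ stretched — rather
than the specific integers, which a user may retune freely as long as χ
stays non-increasing with χ(1) > 0.

Unreachable pairs take the style's repulsive floor. This is a choice the
cost model itself does not dictate; giving disconnected components mutual
repulsion makes them drift to separate regions instead of overlapping
arbitrarily.

### Module boosts

When functional-module labels are available, adding a positive constant to
`w_ij` for same-module pairs makes modules aggregate. Two variants are
exposed, because both are useful in practice: a distance-filtered boost
(e.g. `delta = 10` restricted to pairs at graph distances 2–3, which
tightens modules without distorting the already strongly attracting
distance-1 pairs) and an unfiltered boost within selected modules (e.g.
`delta = 15` on every pair of one subsystem of interest, which gathers
that subsystem into a single block). Nodes labeled `"unassigned"` never
receive a boost: the label means "membership unknown", and gluing unknown
nodes to each other would fabricate structure.

## The optimizer

```
R <- random layout;  R <- neighborhood_test(R)
repeat niter times:
    R' <- neighborhood_test(perturb(R, p))
    if cost(R') < cost(R):  R <- R'
```

**Neighborhood test.** Nodes are swept in index order; each node is
offered every vacant cell of its Moore (8-cell) neighborhood and takes the
best strictly-improving move, with ties broken by the fixed order N, NE,
E, SE, S, SW, W, NW. Sweeping repeats until a full sweep moves nothing, at
which point no single-node move to an adjacent vacant cell can lower the
cost — a certified local minimum. Strict improvement plus a deterministic
tie-break rules out cycling. The sweep order, best-improvement rule and
tie-break are implementation choices the cost model leaves open; they are
fixed as documented so that runs are exactly reproducible. A von Neumann
(4-cell) neighborhood is available as an option.

**Perturbation.** Each node, visited in index order, moves with
probability `p` to a uniformly chosen vacant neighbor cell; vacancy is
evaluated at move time, so collisions are impossible by construction and
the one-node-per-cell invariant is maintained. A node with no vacant
neighbor stays put. `p = 0` leaves the layout untouched; `p = 1` moves
every node that can move. Intermediate values retain part of the previous
optimization effort — the search "remembers" good substructure while
escaping the local minimum.

**Acceptance.** A perturbed-and-reoptimized candidate is accepted only on
a strict cost decrease, so the accepted-cost trace is non-increasing by
construction. The initial random layout is locally optimized once before
the loop, making the trace monotone from its first recorded value.

**Cost evaluation.** Moving one node changes only the `n − 1` terms
involving it, so move deltas are computed incrementally in O(n) (exact
64-bit integer arithmetic; no floating-point tolerances are needed
anywhere). Empirically the number of delta evaluations per run grows
roughly linearly in `n` (log–log slope ≈ 1.1 over n = 50–400 on the
planted-partition networks below), and since each evaluation is O(n) the
wall-clock time grows roughly quadratically.

### Parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `p` | 0.7 | perturbation probability per node and iteration; performance is not very sensitive in the 0.3–0.7 range, and the upper end explores more aggressively |
| `niter` | 60 | perturbation restarts; improvements become rare beyond this, and the trace shows diminishing returns well before |
| `occupancy` | 0.25 | fraction of grid cells occupied: side = ⌈√(n/occupancy)⌉. A quarter-full grid leaves enough vacancy for nodes to slide past each other; higher values give tighter drawings but slower, worse optimization |
| `style` | `"common"` | see the style table above |
| `seed` | none | one RNG stream drives initialization and all perturbations, so a fixed seed makes the whole fit (and all written outputs) bit-identical |

Adaptive stopping ("stop when improvements become rare") is intentionally
not implemented: a fixed `niter` keeps runs comparable and reproducible,
and the stored trace lets users judge convergence after the fact.

## Synthetic test networks

Real curated pathway maps cannot ship with the package, so all tests run
on planted-partition graphs (`synth_network()`): modules of given sizes
with independent within-module edge probability `p_in` and cross-module
probability `p_out ≤ p_in`, optionally bipartite (edges only between
metabolite- and reaction-class nodes). Ground-truth module labels come for
free, which is what the module-cohesion checks need.

Two fixed fixtures (`fixture_network()`) emulate the scale of genome-
derived demonstrations: 290 nodes in 3 modules (sizes 100/95/95,
`p_in = 0.07`, `p_out = 0.002`, bipartite) and 677 nodes in 7 subsystems
(sizes 120/110/100/95/90/80/60, `p_in = 0.06`, `p_out = 0.0015`) plus 22
unassigned reactions wired to three random metabolites each. The edge
probabilities were chosen once to give mean degree ≈ 3–4, the sparsity
typical of currency-filtered metabolic bipartite graphs, and internal
fixed seeds make the fixtures deterministic without disturbing the
caller's RNG state.

What the generator does *not* emulate: the heavy-tailed degree
distribution of real metabolite usage, stoichiometry, reaction
reversibility, and the nested/overlapping structure of real subsystems.
Passing tests therefore demonstrate the optimizer's contracts (optimality
on enumerable instances, certified local minima, monotone acceptance,
style ordering, cohesion under boosts) on networks of realistic size and
sparsity — not that any particular biological map is drawn "correctly",
which is ultimately a judgment about the curation, not the algorithm.

## Numerical and degenerate-input choices

- **Integers throughout.** Coordinates, graph distances, χ values and
  boosts are integers; costs are exact 64-bit sums, so equality and strict
  inequality comparisons are safe.
- **Self-loops** are dropped (with a warning) on input: the cost is
  defined on pairs of distinct nodes. A node named only by a self-loop is
  kept as an isolated node.
- **Isolated nodes** are retained and placed like any other node; under
  the common style their repulsive weights push them to the periphery.
- **Duplicate edges** in either orientation collapse to one unordered
  pair.
- **A single node** is a valid network: its layout has cost 0.
- **Full grids** (`occupancy = 1`) are legal; the optimizer then simply
  cannot move anything and returns the initial placement.
- **Currency metabolites** are matched case-insensitively against the
  stoplist; entries absent from the network are ignored silently, since
  stoplists are generic while networks are specific.

## Validation battery and problem sizes

The acceptance script (`scripts/acceptance.R`) recomputes, from scratch:
optimality against exhaustive placement enumeration (100 seeded runs over
four instances of ≤ 4 nodes on ≤ 3×3 grids); the single-move local-minimum
certificate on 50 random instances of up to 50 nodes; exact delta-cost
agreement on 200 random moves; monotone traces for 20 seeded runs of the
290-node fixture; style bounding-box ordering and the boost's cohesion
improvement (10 seeds each on the 290-node fixture); the evaluation-count
scaling exponent over n ∈ {50, 100, 200, 400}; and complete default-
parameter layouts of both fixtures. These sizes keep the whole battery
around half a minute on one core while still exercising every contract at
the fixtures' full scale.

## Known limitations

- Edge–node and edge–edge crossings are not penalized; occasional
  crossings through unrelated nodes do occur. Avoiding them properly
  requires accounting for node sizes, which the point-node model ignores.
- Edges are drawn as straight lines; no bundling or curving.
- The optimizer is stochastic: different seeds give different (comparable-
  cost) layouts. Global optimality is guaranteed only where enumeration is
  feasible.
- Rendering is static SVG; there is no interactive viewer, zooming or
  label collision avoidance (`label_mode = "listed"` is the manual
  workaround).
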