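---
title: "Methods: ecological security patterns and constrained urban-growth simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ecological security patterns and constrained urban-growth simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(espsim)
```

## Overview

`espsim` chains two analysis tracks that landscape ecologists and land-use
modelers usually run in separate GIS tools:

1. **Ecological security pattern (ESP) construction.** From a categorical
   land-use raster, habitat (woodland + grassland) is classified
   morphologically (MSPA), large well-connected cores are promoted to
   *ecological sources* using the probability-of-connectivity index, sources
   are linked by least-cost *corridors* over a land-use/relief resistance
   surface ranked with a gravity model, and smaller *stepping-stone nodes*
   are added. The union of the three masks is the ESP.
2. **Scenario simulation.** Per-class land demands are projected with a
   Markov chain estimated from two observed epochs, per-cell occurrence
   probabilities are learned by a small neural network from driving factors,
   and a cellular-automata allocator with neighborhood effects, adaptive
   inertia, conversion constraints and roulette competition distributes the
   demands in space — once unconstrained ("natural development") and once
   with the ESP as a restricted area ("ecological security"). Expansion is
   then quantified by direction and by distance from the city center.

## The land-use model

Grids hold six classes — arable (1), woodland (2), grassland (3), water (4),
construction (5), unused (6) — at a projected resolution of 30 m by default.
Areas are reported in km² (`cells × cell_size² / 10⁶`) and hm²
(1 hm² = 0.01 km²). Nodata cells are excluded from every area and zonal
statistic. A single projected CRS is assumed throughout; reprojection is out
of scope.

## MSPA

`classify_mspa()` partitions the habitat foreground into seven mutually
exclusive classes with 8-connectivity. The edge width is measured in
8-connected erosion iterations (Chebyshev distance); the default of 1 cell
corresponds to 30 m. Cores are the erosion residue; islets are foreground
components with no core; edge and perforation form the boundary zone within
the edge width of a core, split by whether the adjacent background is outer
(reachable from the grid border by 4-connected flood fill) or an enclosed
hole. The remaining connector tissue is classified per component: touching
two or more distinct cores makes a bridge, touching one core at two or more
separate contact regions makes a loop, anything else is a branch. Edge takes
precedence over perforation when a cell is within reach of both; thin
connectors are deliberately *not* absorbed by the edge class, otherwise
one-cell-wide bridges could never exist. These conventions follow common
MSPA practice; the partition property (every foreground cell gets exactly
one class) and the core-erosion equivalence are the contracts the tests pin,
since connector subclasses on pathological shapes vary between published
implementations.

## Sources: PC and dPC

For core patches above 100 hm² the probability of connectivity is

$$PC = \frac{\sum_{i}\sum_{j} p^*_{ij}\, a_i a_j}{A_L^2},$$

where $p^*_{ij}$ is the maximum product of direct dispersal probabilities
over all patch paths (solved as a shortest path on $-\ln p$ edge weights)
and $a_i$ are patch areas. Direct probabilities use a negative-exponential
kernel calibrated so that $p(1500\,\mathrm{m}) = 0.5$ — the standard reading
of a distance-threshold/probability parameter pair; a hard-threshold mode is
available as a configuration switch. Patch importance is
$dPC_k = 100\,(PC - PC_{\mathrm{remove},k})/PC$, and cores with $dPC > 1$
become sources, together with non-river water bodies above 100 hm².

Two conventions were genuinely open and are both exposed:

* $A_L$ defaults to the *sum of habitat-patch areas* (the definitional
  reading of "total area of all patches"); the total-landscape-area
  convention of some reference software is available via `al_mode`.
* In $PC_{\mathrm{remove},k}$, $A_L$ stays fixed and only paths through $k$
  are lost, which keeps $dPC \in [0, 100]$ and makes the $dPC > 1$ rule
  scale-free.

A water patch counts as a "river" (excluded from sources, eligible as a
corridor) when its elongation — squared major-axis length over area —
exceeds 10, or when it intersects a supplied river-network mask. The
major-axis length is estimated as the maximum distance between boundary-cell
centers plus one cell.

## Corridors: resistance, least cost, gravity

Resistance combines a land-use score (woodland/water 1, grassland 30, arable
50, unused 90, construction 100) and a topographic-relief score binned as
[0, 8) → 90, [8, 17) → 70, [17, 27) → 50, [27, 37) → 30, [37, 50) → 10,
≥ 50 → 1, weighted 0.7 / 0.3. Bins are left-closed; a relief of exactly 50
scores 1. Cost distances accumulate *mean endpoint resistance × metric step
length* over 8-connected steps (orthogonal `cell_size`, diagonal
`cell_size·√2`) — the common discretization of a continuous path integral.
Corridor endpoints snap to the minimum-cost pair of boundary cells.

Corridor importance uses the gravity model in its definitional form

$$G_{ij} = \frac{\ln S_i}{P_i}\,\frac{\ln S_j}{P_j}\,
           \left(\frac{L_{max}}{L_{ij}}\right)^{2},$$

with $S_i$ the patch area in hm² (so $\ln S_i > 0$ for every ≥ 100 hm²
source), $P_i$ the mean resistance over the patch cells, $L_{ij}$ the
cumulative corridor cost and $L_{max}$ the maximum over all corridors.
Touching patches ($L_{ij}=0$) get $+\infty$ and are always retained.
Corridors are kept top-k by $G$ (k is a configuration choice; the default
14 mirrors a typical regional corridor count) with a minimum-spanning-tree
safety net over the sources so no source is ever isolated. Selected
polylines are buffered by 100 m — about the width of urban protective
forest belts — and rivers longer than 5000 m and wider than 30 m join the
corridor mask directly.

Node selection by expert judgment is not reproducible; the rule-based
surrogate ranks non-source cores by area (optionally within a distance of
the corridor network) and keeps the top n (default 7).

## Demand: Markov projection

`estimate_transition_matrix()` cross-tabulates two epochs into a
row-stochastic matrix; empty rows become identity. Demands at a horizon of
$h$ years from an interval of $\Delta$ years use $M^{h/\Delta}$. Non-integer
powers are taken through the eigendecomposition; when the root is not a
valid stochastic matrix (complex or negative entries), the projection falls
back to whole-interval steps with linear interpolation of the counts —
a documented choice, since nothing canonical fixes how an 8-year matrix
drives a 12-year horizon. Rounded demands are repaired by largest-remainder
apportionment so they sum exactly to the cell total.

## Allocation: the cellular-automata competition

The suitability stage is a single-hidden-layer softmax network (`nnet`, 12
hidden units, weight decay 0.05, 5 % uniform training sample by default).
The decay value matters: with near-deterministic synthetic drivers an
unregularized network saturates (probabilities ~10⁻⁸ off-class), which
starves the roulette of conversion candidates; 0.05 keeps held-out accuracy
far above the majority-class rate while leaving realistic probability mass
on minority classes.

Each sweep of `allocate()`:

1. recomputes neighborhood effects (share of class-k cells in the 3×3 Moore
   window, center excluded, scaled by the class weight — arable 0.1,
   woodland 0.23, grassland 0.35, water 0.5, construction 1, unused 0.4);
2. updates the per-class adaptive inertia from the last two residual demands
   (unchanged when |D| is not growing; scaled by the residual ratio when a
   shortfall deepens or a surplus grows);
3. visits cells of oversupplied classes in seeded random order, draws a
   class by roulette proportional to suitability × (neighborhood + 10⁻⁴) ×
   inertia × transfer permission, and commits only while the drawn class
   still has unmet demand and the cell's class has a surplus.

The 10⁻⁴ neighborhood floor keeps demand-driven growth feasible away from
existing seeds. Restricted cells and forbidden transfers never change —
audited cell-by-cell in the tests. The run stops at tolerance 0 (exact
demand satisfaction), after `max_iterations` sweeps, or after 25 consecutive
sweeps without a commit. The stall exit matters for the constrained
scenario: when the transfer bans make the Markov demand infeasible (e.g.
woodland must shrink but woodland conversions are banned), the allocator
reports a best-effort result with residual diagnostics — which is exactly
the mechanism by which the ecological scenario ends up with less
construction land than the unconstrained one.

## Expansion metrics and validation

From the construction-land center of gravity (unweighted cell-center mean),
the frame is split into four quadrants (ties on an axis join the
counter-clockwise-first quadrant) and concentric 5-km rings (12 by default;
cells beyond the outermost ring are excluded as "outside"). Per zone and
epoch the class area and proportion are tabulated, and per period the
annual increase index $AI = (A_{end}-A_{start})/d$ (km²/yr) and average
annual growth rate $AGR = 100\,[(A_{end}/A_{start})^{1/d}-1]$ (%/yr).
Useful identities the tests verify: AI is duration-weighted additive over
sub-periods, and $(1+AGR_1/100)^{d_1}(1+AGR_2/100)^{d_2} = A_{end}/A_{start}$.

Hindcast validation samples 10 % of cells uniformly and reports Cohen's
kappa, overall accuracy and per-class recall from the confusion matrix.

## The synthetic generator

Because the original input rasters are not redistributable, the
`synthetic_data` module generates study systems with the statistical
structure the method assumes:

* **Landscapes**: one Gaussian-filtered noise field per class; cells are
  assigned by largest-remainder quota in decreasing share order, so realized
  shares match the targets to rounding while patches stay spatially
  coherent. The default latent range of 12 cells at the 200×200 / 30 m
  default shape produces a handful of habitat patches of order 10²–10³ hm² —
  large enough that the 100 hm² core threshold and the dPC rule are
  exercised, mirroring (at reduced extent) a study area whose sources are a
  few large patches.
* **Epoch sequences**: per-cell Markov transitions under a known matrix. A
  3×3 kernel biases conversions toward cells adjacent to the target class
  (urban growth clumps); the kernel preserves each row's total
  leave-probability. Tests that compare empirical frequencies against the
  matrix run with the kernel disabled — the i.i.d. mode is the verifiable
  limit.
* **Driving factors**: nine layers (elevation raised under woodland, slope,
  focal relief, distances to synthetic river/road/railway/residential masks,
  night light and population density decaying with distance to
  construction), min-max normalized to [0, 1]. The construction-linked
  layers give the suitability network real signal to learn.

What the generator does **not** emulate: real terrain morphology,
calibrated night-light radiometry, historical policy shocks, or the spatial
heterogeneity of a specific city. Passing tests therefore demonstrate the
correctness and internal consistency of the algorithms under controlled
conditions, not predictive skill on any particular real landscape.

## Numerical choices and problem sizes

* Direct dispersal probabilities below 10⁻⁹ are pruned from the path graph.
* p = 1 links (touching patches) get an ε = 10⁻¹² edge weight on the
  $-\ln p$ graph so they survive the adjacency representation.
* The relief focal window defaults to 3×3.
* The demo/test problem sizes: module tests run on grids between 5×5 and
  100×100 with exhaustive oracles (brute-force distance scans, explicit
  shortest-path graphs up to 400 cells, simple-path enumeration up to 6
  patches); the end-to-end checks and the acceptance script run the full
  pipeline at the 200×200 default, which completes in well under a minute
  per scenario on one CPU.

## Known limitations

* Connector subclasses (bridge/loop/branch) use simplified component-level
  rules, not geodesic skeleton analysis; they can differ from
  reference-software output on contrived shapes.
* The gravity-model corridor count and the node count are configuration
  choices, not emergent quantities.
* The Markov demand ignores exogenous drivers (policy, economy); under
  constrained transfer matrices it can be infeasible, and the allocator then
  reports the feasible best effort.
* One CRS, one resolution; no reprojection or resampling beyond
  nearest-neighbor refinement.
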