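---
title: "Attention-field swarms: model, metrics and design choices"
author: "swarmattn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-field swarms: model, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`swarmattn` simulates a group of `P` point agents moving continuously on a
square arena of side `L`. The only interaction is a pairwise
attraction/repulsion toward a *single* neighbour, selected through a limited
angular attention field:

1. Agents update asynchronously. One time unit (a *sweep*) is `P`
   single-agent updates; the agent for each update is drawn uniformly at
   random with replacement.
2. The selected agent draws a gaze direction uniformly on `[0, 2π)`. Its
   attention field is the closed angular sector of amplitude `α` bisected
   by the gaze. The agent looks for the nearest neighbour inside that
   sector; if the sector is empty it stays put for this update.
3. Let `d` be the distance to that neighbour and `D` the stress-zone
   radius, which doubles as the ideal inter-individual distance. If
   `d > D` the agent steps a distance `v` straight toward the neighbour;
   if the step would enter the stress zone it stops exactly on the circle
   of radius `D` around the neighbour. If `d < D` it steps `v` straight
   away, stopping exactly at `D` if it would overshoot. At `d = D` it does
   not move.
4. With direction noise `η > 0`, the movement direction is rotated by an
   angle drawn uniformly from `[-ηπ, +ηπ]` before the step; the same
   stop-on-the-`D`-circle rule is applied along the noisy path (the agent
   halts where its path crosses the circle). `η = 0` is noiseless and
   `η = 1` makes the direction fully random.
5. Agents stop at the arena boundary (coordinates are clamped to
   `[0, L]`). In the regimes studied the swarm contracts away from the
   walls, so the boundary rule is immaterial; runs count clamp events so
   this can be verified.

`α = 2π` removes the attention restriction and reproduces the classical
move-toward-nearest-neighbour rule of the selfish-herd literature, which
is known to fragment groups instead of aggregating them. The scientific
point of the model is that restricting attention (`α` well below `2π`)
turns the same elementary rule into one that produces a single, dense,
hexagonally ordered aggregate.

A run ends in a *quasi-stationary state* when no agent position changes
during `qs_window` consecutive sweeps, or at the `max_sweeps` cap
(reported as non-convergence, not an error). A quasi-stationary state may
be a true *absorbing state*, in which every pair of topological
neighbours (Voronoi polygons sharing an edge) sits at distance exactly
`D`; `is_absorbing()` tests this.

## Parameters and defaults

| parameter | meaning | default | units |
|---|---|---|---|
| `P` | group size | 91 | individuals |
| `L` | arena side | 1.74 | length |
| `D` | stress-zone radius / ideal distance | 0.1 | length |
| `v` | step per time unit | 0.0112 | length / sweep |
| `alpha` | attention-field amplitude | `pi/2` | rad |
| `eta` | direction-noise strength | 0 | – |
| `qs_window` | quiescence window | 100 | sweeps |
| `max_sweeps` | horizon cap | 60000 | sweeps |

The `P`, `L`, `D`, `v` defaults reproduce the standard study conditions of
the model: density `P/L² ≈ 30` agents per unit area, i.e. a typical
initial nearest-neighbour distance comparable to `D`. In the biological
reading (a startled crab aggregation), `D` is the mean inter-individual
distance after an attack, `v` the mean attack speed, and one sweep is of
the order of a second.

Two constants are genuinely open implementation choices and are therefore
configurable rather than hard-coded:

* `qs_window = 100` sweeps. The detector needs a window long enough that
  "nobody moved" is not a sampling accident of the random agent
  selection; 100 sweeps is ~9100 consecutive no-move updates for the
  default `P`, making a false positive practically impossible.
* the no-move dead band `dtol = 1e-12` around `D`. Stops land on the
  `D`-circle up to floating-point rounding; without a dead band an agent
  sitting at `D ± 1` ulp would jitter forever and quiescence would be
  unreachable. `1e-12` is far below any physical scale of the model
  (`v`, `D`) and far above double rounding error.

### Agent selection

Selection is uniform *with replacement* (`P` draws per sweep); a
permutation mode (`select = "permutation"`) is provided for sensitivity
checks. With-replacement random-sequential updating is the standard
reading of asynchronous dynamics where "an agent is randomly selected" and
the time unit is defined as one updating of all agents.

### A geometric fact about the lattice fixed point

A perfect triangular lattice with spacing `D` is a fixed point of the
noiseless dynamics whenever `α ≥ π/3`: any sector that contains a
second-shell bearing (distance `√3·D`, bearings midway between first-shell
bearings) also contains a flanking first-shell neighbour at distance
exactly `D`, which is nearer and therefore selected. For `α < π/3` a
narrow gaze can isolate a second-shell neighbour and trigger an attraction
move, so the crystal is *not* absorbing below `π/3`. This is why the
ordered phase can only exist above a critical attention angle, and the
property tests assert the fixed point exactly on `α ≥ π/3` and the
counterexample below it.

## Order metrics

All metrics are pure functions of a point configuration.

**Topological neighbours.** Two agents are topological neighbours when
their Voronoi polygons share an edge of positive length. Cells are built
by incremental half-plane clipping against bisectors in order of
increasing distance, with an early stop once all remaining points are
farther than twice the cell circumradius; each cell edge remembers which
neighbour's bisector created it. The construction is cross-checked in the
tests against an independent bisector-interval oracle and against
`deldir`.

**Sixfold order `Ψ6`.** Per agent, `ψ6(i) = N_i⁻¹ Σ_j exp(6iθ_ij)` over
topological neighbours, `θ_ij` the bond angle to a fixed axis; the global
parameter is the modulus of the agent average. It is 1 exactly on a
triangular lattice and of order `n^{-1/2}` for random points. Two rim
conventions exist because rim cells have distorted bond counts:

* `"clipped"` — polygons clipped to the box, all agents averaged. Used in
  parameter sweeps, where comparability across `α` matters more than the
  absolute ceiling.
* `"interior"` — polygons clipped to the convex hull of the points,
  averaging only agents whose cell does not touch the hull. Under this
  convention a finite crystal patch scores exactly 1, and the value is
  invariant under global rotations and translations (the hull moves with
  the points, so the averaged set is unchanged).

**Translational order `T`.** The mean, over agents, of the number of
individuals inside a circle of radius `r_T` centred on each agent,
counting the focal individual. The radius must separate the first lattice
shell (`D`) from the second (`√3·D ≈ 1.73 D`); the default `r_T = 1.3·D`
sits between them, so a crystal interior scores 7 (self plus six
neighbours) and isolated pairs score 2. The choice within `(D, √3 D)` is
a convention and is exposed (`r_T_factor`); note that in fragmented
states the value is sensitive to it, because loose groups of 3–5 agents
contribute counts between 2 and 5 — larger radii inflate the plateau.
An exclusive variant (`include_self = FALSE`) is available.

**Domains of danger.** Under the selfish-herd reading, an agent's Voronoi
cell area is its predation-risk proxy. For a compact swarm inside a much
larger arena, cells clipped to the full box credit rim agents with empty
space and swamp the signal, so the package's *occupied-region* convention
clips cells to the convex hull of the swarm inflated by `D/2` (Minkowski
sum with a disk, approximated by a 16-gon). The plain box clip is also
provided. `area_reduction()` compares mean areas between two
configurations under this convention, so compaction registers as a
positive fraction; the ideal packed aggregation (triangular lattice of
side `D`) bounds it at about `1 − (√3/2)·D²·P/L² ≈ 0.74` for the default
parameters.

**Clusters.** Connected components of the graph joining pairs closer than
`link_dist` (default `1.5·D`, stated in outputs since no operational
cluster definition is canonical).

## Experiments

Every experiment is a pure function of its parameters, grids, replicate
count and a master seed: replicate seeds are derived by hashing the *grid
values* (not their positions), so grids can be extended or reordered
without perturbing existing cells, and reruns are byte-identical.

* `sweep_alpha()` — runs replicates to quasi-stationarity per attention
  angle and aggregates the metrics, the domain-of-danger reduction, the
  convergence probability and the fluctuation (standard-deviation) peaks
  that mark the order–disorder boundary. Non-converged replicates are
  kept with their final state and flagged, never silently dropped.
* `sweep_speed()` — convergence time against step length for several
  population sizes (the box is rescaled to hold density fixed), the
  optimal speed per population, and a log–log power-law fit of the
  convergence time at the optimum.  Censored (capped) runs are counted
  separately and never averaged into `t_conv`.
* `sweep_noise()` — a fixed horizon per noise strength (no
  quasi-stationarity requirement), the order parameters on the final
  state, and the `η` at which `Ψ6` crosses 0.5.
* `herd_scenario()` — the startled-aggregation scenario (`P = 90`, small
  `α`, mild noise `η = 0.1` by default), tracking the total occupied area
  `A(t)/A(0)` per sweep.

### Quasi-stationarity in practice, and the horizons used

Exact quiescence is demanding: it requires every agent's distance to any
neighbour it could possibly select to equal `D` within the dead band —
effectively a defect-free crystal. Small swarms (`P ≈ 20`) at the
standard density reach it in a few thousand sweeps; at `P = 91` the
system typically spends a long time in a highly ordered but still slowly
rearranging state, and exact convergence within a bounded horizon is a
matter of chance. The package's experiment defaults therefore cap runs
(60 000 sweeps by default; the acceptance protocol uses 150 000 for the
area-reduction sweep) and report capped runs as censored. The
configurations at the cap are quantitatively close to the asymptotic
ones — the occupied-area reduction, for example, creeps up by only about
one percentage point between horizons of 60 000 and 150 000 sweeps — so
capped summaries slightly *understate* the asymptotic compaction. The
problem sizes used in the tests (small `P` for convergence-sensitive
checks, 10–20 replicates per grid value) were chosen as the smallest
that make the qualitative claims statistically stable.

## What the generator does and does not emulate

The uniform initial condition and the parameter defaults emulate the
study conditions of the model: a startled group at a realistic density.
Passing tests therefore show that the *model* behaves as described under
those conditions — four phases as `α` grows (dense disorder, crystal,
low-ordered with holes, fragmentation), a noise-driven order–disorder
transition, fast initial shrinkage of the domain of danger. They do not
show anything about real animal trajectories: there is no inertia, no
heterogeneity among individuals, no predator, no directed collective
drift, and the movement rule is memoryless. The crab parameterisation is
a qualitative mapping of units, not a fit to field data.

## Numerical choices

* Sector membership uses the closed sector; equidistant candidates
  resolve to the lowest agent index. Both choices are measure-zero and
  fixed for determinism against the brute-force oracle.
* Stops on the `D`-circle renormalise the final position radially so the
  distance is exact to one ulp; together with the `dtol` dead band this
  makes the absorbing state reachable in floating point.
* Voronoi clipping tolerances scale with the region size (`1e-10·scale`
  for vertex classification, `1e-8·scale` for the positive-edge-length
  test), so co-circular degeneracies (four points on a square) do not
  produce spurious adjacencies.
* Degenerate metric inputs (fewer than three points, collinear
  configurations) raise explicit errors; the absorbing-state test reports
  them as "not absorbing" since no tessellation exists.
* All randomness flows through R's RNG (including inside the compiled
  core), so `set.seed()`/`params$seed` fix trajectories bit for bit.

## Known limitations

* The quiescence window and the `T` radius are conventions; published
  analyses of this model family do not pin them down numerically, and
  quantities in fragmented states (the `T` plateau in particular) shift
  by a few tenths under legitimate alternative radii.
* The phase boundaries in `α` are reported as empirical crossings
  (`Ψ6 = 0.5`; multi-cluster majority), not constants: they depend on
  density, and the package makes no claim about their exact locations.
* At `P = 91` exact absorbing states are reached only occasionally within
  affordable horizons, so crystal-phase summaries at a cap mix perfect
  and slightly defective configurations.
* Runtime grows as `P²` per sweep (sector search over all agents); the
  implementation is adequate for `P` up to a few hundred, not thousands.
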