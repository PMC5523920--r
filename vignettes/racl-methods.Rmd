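---
title: "Planning tiered CD4 laboratory networks with raclnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning tiered CD4 laboratory networks with raclnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raclnet)
```

## The planning problem

National CD4 programmes face a placement trade-off: centralising testing
into few high-throughput laboratories improves cost per test but pushes
remote clinics beyond an acceptable sample travel time, while
decentralising improves access at the cost of many small, inefficient
sites. `raclnet` frames this as a capacitated set-covering
location-allocation. Given a table of health facilities (clinics,
community health centres, hospitals) with coordinates and daily CD4 test
demand, a subset of which are candidate laboratory sites, and a
travel-time threshold $T$ (hours), the solver selects the minimum number
of laboratories such that every facility cluster can reach one within
$T$, assigns clusters to laboratories, and designates clusters no
laboratory can reach as point-of-care (POC) testing sites.

The pipeline has four stages:

1. **Clustering.** Facilities within `cluster_radius_km` (default 5 km)
   of a cluster leader are merged into one demand point. This shrinks the
   instance the solver sees — co-located town facilities behave as a unit
   — without materially changing travel times, since the radius is small
   against the 2–4 h thresholds of interest.
2. **Drive-time calibration.** Great-circle distances are cheap to
   compute for every cluster–candidate pair; realistic drive times are
   not. A linear model $t = \beta_0 + \beta_1 d$ is fitted by ordinary
   least squares on a *sampled* set of pairs with observed drive times
   (in practice obtained from a routing service for a representative
   sample of distances), then applied to the full distance matrix.
3. **Set-covering solve.** A candidate *covers* a cluster when its
   predicted travel time is at most $T$. The solver picks the fewest
   candidates whose coverage sets include every coverable cluster;
   clusters with no covering candidate become POC sites.
4. **Capacity planning.** Each selected laboratory's allocated daily
   volume is translated into a service tier, an analyser platform
   configuration, the number of configuration units, and bench width.

## Model assumptions

- **Straight-line distance as the covariate.** Distances are haversine
  great-circle kilometres on a sphere of radius 6371 km. Planar
  arithmetic on raw degrees would distort distances at country scale;
  road-network routing is deliberately out of scope — its information
  content enters through the fitted slope $\beta_1$, which absorbs the
  average road-circuity factor.
- **A single pooled time model.** One national $(\beta_0, \beta_1)$ is
  fitted. The intercept captures fixed urban/loading delay and is
  retained rather than forcing the fit through the origin; negative
  predictions at very short distances are clipped to zero. A negative
  fitted slope is rejected outright as evidence of a corrupt sample.
- **Demand is deterministic and wholly assigned.** Each cluster's demand
  (sum of member facilities' daily tests) is assigned to exactly one
  laboratory — no splitting — which matches how courier routes are
  actually organised.
- **Capacity is unlimited by default.** The scenarios of interest let
  platforms scale to demand (the busiest planned laboratory runs at
  several times any current site's throughput, and the planner answers
  with more instrument units). A finite `capacity_per_lab` mode exists;
  when enabled, a laboratory's assigned volume may not exceed it, and
  clusters that cannot be placed become POC sites (greedy) or render the
  instance infeasible (exact, reported with the binding clusters).

## The solvers

`solve_exact()` searches candidate subsets in order of increasing
cardinality, starting from a lower bound given by a greedily-built set of
pairwise-incompatible clusters (no candidate covers any two of them, so
each needs its own laboratory). The first cardinality admitting a
feasible subset is optimal; among feasible subsets of that size the one
with the smallest total assigned distance wins (the primary objective —
fewest sites — leaves ties that would otherwise be broken arbitrarily).
Feasibility under finite capacity uses the same deterministic assignment
rule as the final allocation: clusters in demand-descending order, each
to its nearest selected laboratory (by time) with spare capacity. The
exact solver refuses instances above `exact_limit` (default 20)
candidates.

`solve_greedy()` repeatedly selects the candidate covering the largest
currently-uncovered demand (ties: most uncovered clusters, then smallest
candidate id). It carries the classical set-cover guarantee of at most
$(1 + \ln n)$ times the optimal count and handles national-scale
instances in seconds. The test suite validates the exact solver against
an independent exhaustive-enumeration oracle on hundreds of random
instances with up to 12 candidates, and checks the greedy bound against
the exact optimum on the same instances.

A note on monotonicity in $T$: POC counts never increase as $T$ grows
(the structurally-uncoverable set can only shrink). Laboratory counts are
non-increasing in $T$ whenever the coverable set is unchanged — feasible
covers for a larger $T$ nest inside those for a smaller one — but a
cluster that flips from POC to coverable as $T$ grows can force an
*extra* laboratory. The tests therefore assert lab-count monotonicity on
instances whose clusters are all coverable at the tightest threshold,
which is also the regime the national scenarios (where the selected count
falls 61 → 41 → 15 as $T$ goes 2 → 3 → 4 h) occupy.

## Tunable parameters

| Parameter | Units | Default | Rationale |
|---|---|---|---|
| `T` | hours | per scenario (4 / 3 / 2) | one-way travel-time bound consistent with a 24 h result turn-around |
| `cluster_radius_km` | km | 5 | merges same-town facilities; small against $T \cdot$ speed |
| `capacity_per_lab` | tests/day | `Inf` | scenarios size platforms to demand; finite mode available |
| `exact_limit` | candidates | 20 | subset search is exponential in the candidate count |
| sampling `fraction` | proportion | caller-set | share of distance-matrix cells with observed drive times |

The stratified sampler (`sample_pairs()`) draws equal counts per distance
decile so the regression is informed across the whole range rather than
dominated by the many short pairs; simple random sampling is available by
flag. Matrices under 10 cells are taken whole.

## Capacity rules

Service tiers are half-open daily-volume bands: Tier 1 true POC
(< 3), Tier 2 POC hub (< 10), Tier 3 community laboratory (< 100), Tier 4
district laboratory (100–299), Tier 5 high-volume centralised laboratory
(≥ 300), with sites at ≥ 600 tests/day flagged as consolidation
("super-laboratory") candidates.

Platform selection is a band lookup (fully configurable via
`platform_defaults()`): the single-cytometer XL MCL up to 200 tests/day,
then bundled preparation + cytometer configurations 1+1, 2+1 (unit bench
width 5.27 m) and 2+2 (6.78 m). The 2+2 planning capacity is
`daily_throughput(2)` = 2 preparation systems × 54 samples/h × 10 h =
1080 tests/day, the only value consistent with every published instrument
quantity we reproduce; unit counts are `ceiling(volume / 1080)`, so
provisioned capacity never falls below allocated volume. Band edges
(200 / 430 / 551) are interpolated between adjacent published rows; the
published tables themselves assign 346/day to a 2+1 in one scenario but
420/day to a 1+1 in another, so platform choice there was not a pure
function of volume — the finer-grained assignment is the default and the
table is an explicit argument everywhere.

Two reporting conventions are deliberate: bench widths round to the
nearest metre *half away from zero* (6.78 → 7, unlike banker's rounding),
and the headline percentage reduction is *truncated* to one decimal
(44/59 = 74.576…% prints as 74.5%), since that is how the reference
figures were evidently produced. `pct_volume_change()` itself returns the
exact value.

## The synthetic generator

`generate_network()` emulates the *structure* of the real national
dataset, which is not publicly deposited: ~3200 facilities scattered
(Gaussian, sd 4 km) around ~120 towns placed uniformly in a
South-Africa-sized bounding box; facility kinds drawn as 67% clinics, 8%
community health centres, 25% hospitals; Poisson daily volumes with means
25 / 60 / 120 tests/day by kind (giving annual national totals of the
right order); 62/3200 of facilities flagged candidate laboratories,
preferentially at hospitals. `generate_drive_times()` emits calibration
samples from a known linear truth (default 0.2 h + 0.015 h/km ≈ 67 km/h
straight-line speed) plus Gaussian noise (sd 0.05 h), floored at zero.
Everything is deterministic per seed.

What the generator does *not* emulate: the real coastal/inland population
gradient, road-quality geography (noise is homoscedastic), and the
spatial correlation between demand and candidate density. Passing tests
therefore demonstrate algorithmic correctness — optimality, feasibility,
invariants, calibration recovery — not that synthetic scenario counts
match the published national ones (15 / 41 / 61 laboratories), which
depend on the real facility locations. Hand-built fixtures
(`fixture_presets()`) cover the behaviours that matter at desk scale:
`three_towns` is exactly solvable and oracle-checked, `colesberg_like`
exercises same-town clustering, and `remote_fringe` has a settlement
341 km from every candidate — POC at $T = 2$ h, absorbed at $T = 4$ h
under its 0.01 h/km truth model.

## Numerical choices and degenerate inputs

- Clustering iterates facilities in ascending id order and assigns to the
  *first* in-radius leader: fully deterministic, O(n·k), and idempotent on
  mutually-distant leaders. The radius bounds leader-to-member distance
  (not cluster diameter, which may reach twice the radius).
- OLS is delegated to `stats::lm`; fits require ≥ 2 points and ≥ 2
  distinct distances ("degenerate design" otherwise). R² is computed from
  residual and total sums of squares directly.
- Tie-breaks are total assigned distance (exact solver), then
  lexicographic candidate ids; the greedy selection breaks ties by
  uncovered-cluster count, then id. Repeated runs are byte-identical.
- An empty facility table, an empty candidate list, duplicate ids and
  out-of-range coordinates all fail fast with the offending ids named.
- Test problem sizes: oracle validation uses 200 random instances of up
  to 20 clusters × 12 candidates (the exhaustive oracle enumerates all
  2¹² subsets); calibration recovery uses n = 500 noisy samples;
  generator checks run at the full n = 3200.

## Known limitations

- The linear time model underestimates travel where roads are poor, so
  coverage near the threshold boundary is optimistic there; the original
  analysis notes the same limitation of its sampled drive times.
- Exact optimality is only practical to a few tens of candidates; beyond
  that the greedy bound is the guarantee.
- Multi-period planning, stochastic demand, cost modelling and
  multi-assay co-placement are out of scope.
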