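---
title: "Colony-based habitat-use modelling for central-place foragers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Colony-based habitat-use modelling for central-place foragers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpfhabitat)
```

## The problem

Breeding seabirds and pinnipeds are central-place foragers: they commute
between a fixed colony and at-sea foraging grounds, so their distribution is
shaped jointly by habitat quality, the travel cost of distance from the
colony, and competition with animals from neighbouring colonies. Tracking
data exist only for a subset of colonies, yet management questions (where do
multiple species concentrate? which areas matter for *all* colonies?) need
predictions for every colony. `cpfhabitat` implements the full chain from raw
tracking fixes to multi-species probability-of-use maps:

1. **Track processing** — satellite-count and speed filtering, trip
   delineation by distance to the colony, gap splitting for taxa with sparse
   uplinks, and hourly regularization (linear, or a continuous-time
   correlated random walk smoother for noisy Argos data).
2. **Space use** — kernel utilization distributions (UDs) masked off land,
   with the bandwidth set to the area-restricted-search (ARS) scale derived
   from first-passage-time (FPT) analysis; 50% isopleth core areas; overlap
   counts; and trip-resampling representativeness curves.
3. **Habitat design** — a case-control (presence / pseudo-absence) table with
   least-cost distance, null-density competition, and static plus dynamic
   environmental covariates, standardized and screened for collinearity.
4. **Habitat model** — binomial GAMs with shrinkage cubic splines, forward
   stepwise selection ordered and validated by leave-one-colony-out
   cross-validated AUC.
5. **Prediction surfaces** — the case-control-corrected probability-of-use
   equation applied per colony (tracked or not), aggregated to species,
   cumulative and overlap maps, optionally weighted by colony size.
6. **Synthetic world** — a seeded generator of archipelagos, environmental
   fields and habitat-biased central-place tracks with *known* preference,
   so every stage is testable end to end without any external data.

## The model

Use is contrasted with availability by a case-control design. For each
observed at-sea position, `ratio = 3` pseudo-absences are placed uniformly at
random in the colony's *accessible region* — sea cells whose least-cost
at-sea distance from the colony is at most `accessibility_factor = 1.1` times
the group's maximum trip distance — and temporally matched by drawing dates
from the presence set. The 0/1 label is modelled as

\[
\mathrm{logit}\, P(\text{use}) = \beta_0 + f_1(x_1) + \dots + f_p(x_p),
\]

with smooth terms \(f_j\) represented as cubic regression splines *with
shrinkage* (`mgcv`, `bs = "cs"`), initially `k = 3` knots. Because the class
balance is artificial (3 pseudo-absences per presence), fitted probabilities
are corrected to be proportional to the probability of use:

\[
\tau(x) = \frac{\exp\{\log[(1-P_a)P_u/P_a] + \hat\eta(x)\}}
               {1 + \exp\{\log[(1-P_a)P_u/P_a] + \hat\eta(x)\}},
\]

where \(P_a = 3/4\) and \(P_u = 1/4\) are the absence and presence
proportions. Two closed forms pin this down: \(\eta = 0\) with
\(P_a = P_u = 1/2\) gives \(\tau = 1/3\), and \(\eta = 0\) with the 3:1
design gives \(\tau = 1/13\); both are verified to `1e-12` in the test suite.

Candidate covariates are the seven the field routinely uses for these
predators: least-cost **distance** to the colony (km), **null density**
(population size / distance², summed over the other colonies, an
intraspecific-competition proxy), **bathymetry** (positive depth, m),
**slope** (degrees), **SST** (°C), **SLA** (m) and **EKE**
(½(U² + V²), m²/s²).

## Key parameters

| Parameter | Default | Meaning |
|---|---|---|
| `ratio` | 3 | pseudo-absences per presence |
| `accessibility_factor` | 1.1 | multiple of max trip distance bounding availability |
| `return_radius` | 2 km (config) | distance to colony closing a trip |
| `min_trip_fixes` | 3 | minimum at-sea fixes per trip |
| `vmax` | 3 / 20 m/s | speed-filter bound, swimmers / flying seabirds |
| `gap_speed` | 6 km/h | sustained swim speed for the gap-splitting rule |
| FPT radii | 1–150 km | evaluation grid for the ARS scale |
| `rep_iters` | 500 | trip subsets per sample size in representativeness |
| `rep_threshold` | 75% | representativeness flag |
| isopleth `level` | 0.5 | core-area mass fraction |
| `k` (knots) | 3 (max 5) | spline basis dimension |
| `vif_threshold` | 3 | collinearity screen |
| `tie_epsilon` | 0.01 AUC | minimum improvement / tie width in stepwise |
| `presence_threshold` | 0.5 | standardized-τ cutoff for overlap counting |

`return_radius`, `min_trip_fixes`, `vif_threshold`, `tie_epsilon` and
`presence_threshold` are assumptions rather than field-standard constants:
no consensus values exist, so they are config-exposed and the overlap map's
sensitivity to `presence_threshold` is part of the test suite.

## Design choices

**Bathymetry sign.** Depth is stored positive (a 400 m shelf edge is
`bathymetry = 400`). Oceanographic rasters are usually negative-down; negate
at the I/O boundary.

**Speed filter.** The classical filter's internals vary between
implementations; here the *later* fix of the worst-violating consecutive pair
is removed, iteratively, until no implied speed exceeds `vmax`. This is
deterministic, idempotent (verified by property test), and keeps the earlier
fix on ties.

**Gap splitting.** A trip is split at a gap when its duration exceeds
`(d_coast(before) + d_coast(after)) / gap_speed` — the round-trip time via the
nearest coast — which reduces to `2 d / speed` when the two coast distances
agree.

**CTCRW smoother.** The regularizer's state-space model is an integrated
Ornstein–Uhlenbeck velocity with isotropic, source-dependent observation
noise, fitted by maximum likelihood (Nelder–Mead on log β, log σ) and
smoothed with an RTS pass; transition moments are exact for irregular
sampling. Per-Argos-class error ellipses are out of scope; one SD per source
is exposed instead.

**Least-cost distances.** Shortest paths over the 8-connected sea-cell graph
(orthogonal steps cost one cell, diagonals √2), computed with `igraph`. The
test suite verifies them against an independent hand-written Dijkstra on 100
random worlds.

**ARS bandwidth.** Per trip, FPT is evaluated on a radius grid and the radius
maximizing `var(log FPT)` across positions is that trip's scale; trips with
no interior maximum (e.g. straight transits) are excluded, and the group
bandwidth `h` is the mean per-trip scale pooled across the group (a
per-colony variant is a config switch). In simulations with search planted
in 10-km-wide patches the recovered scale is one radius-grid step below the
patch width — the variance peak sits at the transition between within-patch
and departure-driven circle crossings — which is the accuracy the tests
assert.

**Isopleth ties.** The core area is the shortest prefix of cells sorted by
density whose mass reaches the level, *including* all cells tied at the cut
density. A perfectly uniform UD therefore returns every cell — a conservative
degenerate case, covered by a test.

**Representativeness.** Mean 50%-UD area over 500 random trip subsets per
sample size, fitted with the two-parameter saturating regression
\(A(n) = A_\infty(1 - e^{-n/c})\) (starting values: max observed area,
`N/3`), value = 100 × observed area / \(A_\infty\), representative at ≥ 75%.
When every subset yields the same area the curve is constant, the regression
is degenerate, and the value is exactly 100 by definition. Percentile CIs and
Monte-Carlo standard errors accompany the curve; near the asymptote the mean
curve fluctuates within Monte-Carlo error, so monotonicity should be judged
against the reported `se`.

**Stepwise selection.** Candidates are first screened by VIF (iteratively
dropping the worst until all ≤ 3), then scored alone by cross-validated AUC,
ordered, and added greedily; a candidate stays only if it improves mean CV
AUC by at least `tie_epsilon`. If the top two single-covariate AUCs are
within `tie_epsilon`, the procedure reruns once per starting covariate and
keeps the better final model. A distance × bathymetry tensor smooth replaces
the two marginals when it improves CV AUC. Knots are raised (3 → 4 → 5) for a
kept term only while a runs test on deviance residuals ordered by that
covariate rejects at α = 0.05. The final model is refit on all rows for
prediction; reported CV metrics come from the selection-time folds. The
operating point for sensitivity/specificity maximizes Youden's J — a stated
assumption, since threshold rules differ between studies.

**Surface standardization and aggregation.** Group surfaces are divided by
their maximum before summing into the cumulative map (each group contributes
a peak of 1); overlap counts cells whose standardized τ reaches
`presence_threshold`. Unweighted multi-colony aggregation takes the cell-wise
maximum (a cell is used if animals from *any* colony use it); weighted mode
is the colony-size weighted mean. Standardization happens after multi-colony
aggregation. Predictions are restricted to each colony's accessible region
and dynamic covariates are averaged over the tracked date window.

## What the synthetic world does and does not emulate

The generator emulates the statistical structure the analysis relies on:
irregular island coastlines; bathymetry deepening offshore with smooth noise;
daily SST/SLA/current fields with spatial correlation; colonies of log-uniform
size on coastal cells; and multi-trip central-place tracks whose step
selection follows `exp(distance_coef * d + f(depth))` with forced colony
return, Argos-like positional error, satellite counts and dropout gaps. It
does **not** emulate eddy dynamics or fronts, behavioural state switching,
tides, or interactions between species; and the occupancy realized by a
biased random walk matches the planted preference only at coarse (decile)
granularity — near the colony, trip geometry (every trip starts and ends
there, and outbound legs must traverse the inner rings) produces a local
bump that a flexible smooth can pick up. Passing the recovery tests
therefore shows the pipeline recovers a known preference from data with the
right correlation structure, not that any particular field system satisfies
the model.

Test problem sizes are chosen to exercise each property at the smallest
scale where it is meaningful: worlds of 70 × 70 cells of 5 km, 4 colonies,
~4,500 fixes and ~250 trips for the end-to-end recovery study (20
replicate seeds for the covariate-retention frequencies), 60 trips × 500
iterations for the representativeness criterion, and ≤ 30 × 30 grids for the
exhaustive Dijkstra and isopleth oracles.

## Numerical notes

- The `N/d²` competition index is floored at half a cell size before
  squaring, keeping the colony cell finite while preserving ordering.
- Standardization uses the sample SD (n − 1); parameters are stored on the
  table and reused at prediction time — predicting from unstandardized
  inputs without stored parameters is an error, not a silent fallback.
- AUC uses midranks, so ties count ½ and the value matches the O(n²)
  pairwise oracle exactly.
- Kernel evaluation truncates the Gaussian at 5h; UD mass is renormalized
  after land masking, and every UD-producing operation re-asserts mass 1
  and land 0.
- FPT circle crossings are linearly interpolated in distance between the
  last inside and first outside position; forward and backward half-times
  are summed, and positions whose circle is never exited are `NA`
  (undefined), never 0.

## Known limitations

No random effects for individual or colony, and no explicit spatial or
temporal autocorrelation terms — cross-validation by colony is the guard
against optimism, as is conventional for datasets of this shape. The CTCRW
smoother uses isotropic observation noise, not per-class Argos error
ellipses. Real-data map projection (e.g. Lambert azimuthal equal-area) is an
I/O concern: the package works in planar km throughout.

## A small worked run

```{r demo, eval = FALSE}
cfg <- demo_config(seed = 42)
res <- run_pipeline(cfg, out_dir = "demo_out")
res$models$diver              # selected terms, CV AUC
res$space$diver$representativeness$value
max(res$cumulative$values, na.rm = TRUE)
```

The same configuration rerun with the same seed reproduces every output
bit-for-bit; `run_manifest.json` records the configuration and seeds of a
run.
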