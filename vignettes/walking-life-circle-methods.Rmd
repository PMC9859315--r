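---
title: "Methods: G2SFCA accessibility and equity of urban green space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: G2SFCA accessibility and equity of urban green space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(greenaccess)
```

## The problem

Urban green space (UGS) — parks, squares and regional green areas — is a
health resource whose benefit depends on whether residents can actually walk
to it. `greenaccess` measures that provision within the *walking life
circle*: the 5-, 15- and 30-minute pedestrian ranges around each residence,
operationalised as network distances of 500, 1000 and 2000 m. (At a nominal
5 km/h, 5 minutes corresponds to roughly 417 m; the 500/1000/2000 m
thresholds are the conventional life-circle radii and are taken as the
operative definition, with the walking speed kept as metadata only.) On top
of the per-unit accessibility scores, the package quantifies how equitably
that provision is distributed (Gini/Lorenz), how each unit compares to the
city-wide per-capita endowment (location entropy), and what fraction of each
sub-district's area and population is effectively served (coverage ratios).

## Demand: population disaggregation

Census population is published per sub-district, while demand is expressed
at residential areas. Under a uniform-density assumption, the population of
residential area $k$ inside sub-district $s$ is obtained by areal weighting:

$$D_k = \frac{RA_k}{RA_s}\, SP_s,$$

where $RA_k$ is the polygon area of unit $k$, $RA_s$ the summed residential
area of the sub-district and $SP_s$ its census population. $D_k$ is kept as
a real number — the formula does not produce integers and every downstream
quantity is continuous; rounding happens only in reports. The split is
exactly conservative per sub-district; sub-districts holding population but
no residential polygon raise an orphan-population warning rather than
silently dropping people. `validate_population_estimate()` compares $D_k$
against surveyed household counts times an average household size (default
3.5 persons) with the symmetric ratio $\min(D_k, \hat D_k)/\max(D_k, \hat
D_k)$; the ratio direction is not fixed by convention anywhere we are aware
of, so the symmetric form — which penalises over- and under-estimation
alike — was chosen and is documented as a choice.

Each residential area's demand point is its geometric centroid; for
non-convex polygons whose centroid falls outside, a representative interior
point on the mid-height scanline is used instead.

## Supply: green spaces and entrances

Green spaces at or above 5 ha (50,000 m²) are entered through explicit
entrances (2–4 boundary points in the synthetic generator); smaller ones
are represented by a single access point at the centroid. Travel to a green
space means travel to its *nearest* entrance.

## Travel distances

The pedestrian network is an undirected weighted graph. Off-network points
are snapped to the nearest point on any edge (perpendicular projection
clamped to the segment, ties broken by the smallest edge id), and the
travel distance between two points is connector + shortest path + connector.
The straight-line connectors are included by default — excluding them makes
buildings far from any road look artificially close — but a switch
(`include_connectors = FALSE`) provides the pure on-network metric.
Unreachable pairs are `Inf`, never a capped finite value, so that decay
weights cannot be silently corrupted by sentinel distances. Snapping to
edges rather than nodes matters most at the 500 m scope, where node-only
snapping would distort small catchments.

## The G2SFCA model

Accessibility uses the Gaussian two-step floating catchment area method.
Distances are weighted by the bounded Gaussian kernel

$$G(d) = \frac{e^{-\frac12 (d/d_0)^2} - e^{-\frac12}}{1 - e^{-\frac12}},
\qquad 0 \le d \le d_0,$$

which equals 1 at the origin and 0 at the threshold. **Step 1** forms, for
each green space $j$ with area $S_j$, the supply–demand ratio over the
demand within its catchment:

$$R_j = \frac{S_j}{\sum_{k:\, d_{kj} \le d_0} G(d_{kj})\, D_k}
\quad \text{(m}^2\text{/person)}.$$

**Step 2** sums the decay-weighted ratios reachable from each demand point:

$$A_k = \sum_{j:\, d_{kj} \le d_0} G(d_{kj})\, R_j.$$

Both steps use the same $d_0$ per scope. A boundary subtlety: the catchment
is defined with $d \le d_0$ while the kernel is stated for $d < d_0$; since
$G(d_0) = 0$ exactly, the two conventions are numerically identical, and the
implementation includes the boundary with zero weight. Green spaces whose
catchment contains no weighted demand have an undefined $R_j$; they are
excluded with a notice and contribute nothing downstream.

$A_k$ has the units and interpretation of effective green space per capita,
and the two-step scheme conserves supply in aggregate:

$$\sum_k D_k A_k = \sum_{j\ \mathrm{served}} S_j .$$

This identity is checked to a relative tolerance of $10^{-6}$ at every
pipeline run and across a 50-scenario test battery; it holds to machine
precision in practice.

## Grading and the per-capita baseline

Accessible units (those with a strictly positive contribution) are graded
into five classes — very low, lower, medium, higher, very high — by
Fisher–Jenks natural breaks: the globally optimal 1-D partition minimising
within-class sum of squared deviations, computed by dynamic programming
over the sorted scores and verified against exhaustive partition search in
the tests. Inaccessible units form their own category and are excluded from
the break optimisation; including their zeros would turn the lowest class
into a zero bucket and misplace every break. Each scope is graded
independently and the break points are logged, so a shared-breaks reading
can be reproduced from the outputs if wanted. When fewer than five distinct
scores are accessible the class count degrades gracefully.

Each score is also compared against the study-wide per-capita green space
$S/P$ (total green area over total census population, m²/person), the
natural yardstick because $A_k$ is itself a per-capita quantity.

## Equity statistics

**Gini/Lorenz.** Units are sorted ascending by per-capita accessibility;
with $W_i$ the cumulative share of the total held by the first $i$ units,
the trapezoidal Gini is

$$G = 1 - \frac{1}{n}\Bigl(2\sum_{i=1}^{n-1} W_i + 1\Bigr),$$

0 under perfect equality and $(n-1)/n$ when one unit holds everything.
Units enter unweighted (one observation per unit) by default; a
population-weighted variant is available behind
`population_weighted_gini = TRUE` but is not the default report. The Gini
is computed at both unit levels: residential areas, and sub-districts with
$A_j$ aggregated as the population-weighted mean of member units (an
independent sub-district-level model run would also be possible; the
weighted mean was chosen because it preserves the conservation identity and
requires no second set of catchments).

**Location entropy.** $AALQ_j = A_j / (S/P)$, graded with fixed half-open
bins $[0,0.5)$, $[0.5,0.75)$, $[0.75,1.2)$, $[1.2,2.0)$, $[2.0,\infty)$
(the published bin notation does not state closure; half-open lower-closed
intervals were adopted so every value lands in exactly one bin). Values
above 1 mark units served better than the city-wide average, and the
population-weighted mean of $AALQ$ equals the served share of supply — at
most 1, with equality when every green space serves someone.

**Coverage.** A residential area is covered at a scope when at least one
green space lies within its threshold. Per sub-district, $T_j$ is the
covered residential area over the sub-district's polygon area and $U_j$ the
covered population over its census population. "Effective service area" is
read as the area of covered *residential* polygons (not green-space service
buffers): the published definition indexes the sum by the residential areas
of the sub-district, and this reading also guarantees $T_j \le 1$ for
non-overlapping residential polygons and $U_j \in [0,1]$. This is an
interpretive choice, recorded as such.

Reported percentages are rounded half-up to one decimal (two where the
source tables use two), matching the convention of the published tables
rather than IEEE half-even rounding.

## The synthetic city

No public dataset accompanies the study design this pipeline implements, so
a seeded generator provides inputs with the structure the analysis assumes:

- **Road network:** a rectangular lattice over the extent (default 12 × 10
  km at 250 m spacing) with 10% of edges deleted at random under a
  connectivity guarantee, perturbing the grid towards a partly redundant
  street mesh.
- **Sub-districts:** rectangles exactly partitioning the extent (default
  39); census totals split by a symmetric Dirichlet draw and conserved to
  the person by largest-remainder rounding. Default total population is 3
  million — chosen so that, with the default green supply, the per-capita
  endowment lands in the single-digit m²/person range typical of dense
  cities.
- **Residential areas:** random rectangles (sides 60–300 m) placed inside
  their sub-district, about 2020 of them, so demand points are contained in
  their sub-district by construction.
- **Green spaces:** 85 by default, areas log-uniform between 0.5 and 50 ha
  so that both size classes are populated roughly evenly around the 5 ha
  threshold. A `clustering` knob sends each green space into the north-west
  quadrant with the given probability (default 0.7): at 0 supply is
  spatially uniform; near 1 it concentrates in one quadrant, reproducing
  the empirically observed regime of many unserved units at 500 m together
  with high Gini values that fall as the travel scope widens.

What the generator does *not* emulate: real street morphology, non-convex
parcels, building heights and non-uniform within-parcel density,
correlation between population density and green supply, and edge effects
from supply outside the study area. Passing tests therefore demonstrate the
correctness and internal consistency of the computations and the
qualitative clustered-supply regime — not calibration to any particular
city's magnitudes.

## Numerical and degenerate-input choices

- Tie-breaks are deterministic everywhere: snapping prefers the smallest
  edge id, the natural-breaks dynamic program takes the first (lowest
  boundary) optimum, and all randomness flows from the single scenario
  seed, restored after use so library calls do not disturb the caller's
  RNG stream.
- Of parallel edges the shorter is kept; self-loops are rejected; edge
  lengths must be positive and no shorter than the straight-line distance
  between endpoints (within 1 µm).
- All-zero accessibility makes the Gini undefined and is an error, as is a
  single-unit Gini; zero-population sub-districts report `U_j` as missing
  rather than dividing by zero; zero-household validation samples score 0
  with a warning.
- Degenerate scenarios (extent smaller than one grid cell, fewer
  residential areas than sub-districts) fail fast with specific errors.

## Problem sizes and runtime

The default study-scale scenario (about 2400 network nodes, 2020 demand
points, 85 green spaces, three scopes) generates in a few seconds and runs
end to end in under ten seconds on one CPU. The test suite exercises the
conservation identity on fifty 2.5 km scenarios of 40–50 residential units
each, brute-force distance/catchment oracles on graphs of up to 12 nodes,
and exhaustive natural-breaks search up to $n = 12$ — sizes at which the
independent oracles are exact and fast.

## Known limitations

- Travel is isotropic pedestrian shortest-path distance: no turn
  restrictions, crossings, slopes or perceived-safety weights.
- The uniform-density disaggregation ignores building floors; the
  symmetric-ratio household validation quantifies, but cannot correct, the
  resulting error.
- Supply is measured by area only; green-space quality and capacity
  constraints are out of scope, as are demographic subgroup analyses.
- The Gini is reported without inferential uncertainty; comparing Ginis
  across scopes is descriptive.
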