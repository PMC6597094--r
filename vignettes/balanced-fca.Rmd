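---
title: "Balanced floating catchment area methods: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Balanced floating catchment area methods: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcatools)
```

## The model

Floating catchment area (FCA) methods estimate spatial accessibility as an
ensemble of two gravity models. The ingredients are population centers
$i = 1, \dots, N$ with populations $P_i$, facilities $j = 1, \dots, J$
with supply $S_j$ (provider units such as physicians), an
origin–destination travel-cost matrix $d_{ij}$ in minutes, and an
impedance function $W(d) \in [0, 1]$, non-increasing in cost, that models
the declining propensity to travel. Writing $W_{ij} = W(d_{ij})$:

* **Step 1 (demand, level of service).** $D_j = \sum_i P_i W_{ij}$ and
  $L_j = S_j / D_j$. $L_j$ resembles a local provider-to-population ratio
  (PPR): supply divided by the population competing for it.
* **Step 2 (accessibility).** $A_i = \sum_j L_j W_{ij}$, the service a
  center can reach.

The classic variants differ only in which weights enter each step:

| method | step 1 weights | step 2 weights |
|---|---|---|
| `2sfca` / `e2sfca` | $W$ (binary / stepwise) | $W$ |
| `3sfca` | $G \odot W$, $G_{ij} = T_{ij} / \sum_j T_{ij}$ | $G^{j} \odot W$ |
| `m2sfca` | $W$ | $W \odot W$ |
| `balanced` | $W^{i}$ (row-standardized) | $W^{j}$ (column-standardized) |

**Why balance?** When catchments overlap, step 1 counts the same people at
several facilities and step 2 hands the same level of service to several
centers. Neither total is conserved: on the package's built-in nine-center
system the binary nominal demand is 9,750 people in a region of 4,500, and
total allocated service is 11.8 per 1,000 where 1.87 exist (both numbers
are recomputed in the test suite). The balanced method standardizes the
impedance matrix instead of re-weighting outcomes: with
$W^{i}_{ij} = W_{ij} / \sum_j W_{ij}$ every covered center allocates
exactly 100% of its population across the facilities it reaches
($\sum_j P_i W^{i}_{ij} = P_i$, a pycnophylactic, i.e. mass-preserving,
allocation), and with $W^{j}_{ij} = W_{ij} / \sum_i W_{ij}$ every
patronized facility allocates exactly 100% of its level of service
($\sum_i L_j W^{j}_{ij} = L_j$). Consequently $L^*_j$ is a genuine local
PPR and $\sum_i A^*_i = \sum_j L^*_j$: accessibility is each center's
*share* of the system's service. The standardized weights sum to one along
their margin and can be read as contact probabilities. The assumption
bought by this is assortative, undifferentiated choice: the population
sorts itself proportionally to the (impedance-weighted) alternatives, which
is reasonable for undifferentiated services (family medicine) and not for
strongly differentiated ones.

## Tunable parameters

* **Impedance.** `impedance_binary(d0)`: a single catchment threshold in
  minutes; everyone inside counts fully, nobody outside counts.
  `impedance_stepwise(breaks, weights)`: a non-increasing staircase,
  weights in $(0, 1]$, zero beyond the last break; brackets are closed on
  the right, so a cost exactly at a break takes the lower bracket's
  (larger) weight. `impedance_gaussian(sigma, cutoff)`:
  $\exp(-d^2 / 2\sigma^2)$, optionally truncated. `gaussian_stepwise()`
  discretizes a Gaussian onto brackets by evaluating it at each upper
  break — the common calibration route when a travel survey suggests a
  median trip duration (use it as $\sigma$, e.g. 15 minutes for a
  mid-sized urban region) but the analysis wants a staircase.
  There is no default impedance: the threshold *is* the substantive
  modelling decision, and results are sensitive to it.
* **Slack factors** (balanced method only): positive multipliers applied
  after standardization, per center (demand) or per facility (supply).
  Slack 1 (default) allocates exactly 100%; 1.10 inflates a unit's
  allocation by 10%, 0.9 deflates it by 10%. They model imperfect sorting
  — incomplete information, bias toward central locations — and are
  deliberately *inputs* (scalar or `(id, factor)` CSV); the package does
  not estimate them from data.
* **Reporting scale** (`scale`, default 1000): levels of service,
  accessibility and disparity are stored per person and reported per
  1,000 population by default. All arithmetic happens at full double
  precision; only file output is rounded (6 significant digits by
  default).

## Numerical and degenerate-input choices

* **Unreachable pairs** are stored as `Inf` cost: a pair missing from a
  long-format cost file is out of every catchment (weight exactly 0 under
  every impedance kind), *not* cost 0, which would silently mean maximal
  weight. Ids are matched as trimmed strings; no fuzzy matching.
* **Uncovered centers / unpatronized facilities** (all-zero weight rows or
  columns) are a legitimate state of a suboptimally configured system:
  standardization returns them as zero and reports their ids in an
  attribute rather than erroring. A facility with zero demand has no
  defined service ratio; its LOS is set to 0 (so it contributes nothing to
  accessibility) and flagged with a warning — never an `Inf` that would
  propagate into totals.
* **3SFCA step 2.** The selection weights are defined with their indices
  reversed in the second step, reflecting catchments floated to centers.
  The package implements this as the column-wise analogue of $G$ computed
  from the same selection impedance $T$ (by default $T = W$; a separate
  Gaussian $T$ can be supplied): $A_i = \sum_j G^{j}_{ij} L^*_j W_{ij}$.
  This is a documented interpretation of a formula whose published
  variants are not mutually consistent; the package follows the symbolic
  definition rather than tuning toward any particular printed table.
* **M2SFCA** squares the weights in step 2 only; step 1 demand is
  identical to the enhanced two-step method under the same impedance.
  With all weights $\le 1$ this can only reduce accessibility, which the
  test suite asserts as a domination property.
* **Standardization** is idempotent, invariant to positive rescaling of
  the weight matrix, and linear in slack; method pipelines always
  standardize the *raw* impedance weights.

## The built-in and synthetic scenarios

Two hand-sized reference systems are built in. `toy_two_clinics()`: three
centers of 100 people, two clinics of 10 physicians, binary (all-ones) and
stepwise weight matrices supplied directly — under the balanced method
both impedances allocate exactly 150 people per clinic.
`simulated_nine_centers()`: nine centers (total 4,500), three clinics
(supply 1, 3, 2; regional PPR 1.333 per 1,000), with binary and stepwise
(0.945 / 0.600 / 0.242) matrices. Both fixtures encode their weight
matrices directly rather than reverse-engineering coordinates, since the
weights, not the geometry, define the system. `export_fixture()` writes
them as CSVs, including a cost matrix labelled synthetic that is
*consistent with* the binary catchments (10 minutes inside, unreachable
outside) so command-line runs with `--impedance binary:15` reproduce the
binary weights exactly.

`random_scenario()` generates property-test scenarios: centers and
facilities uniform on a square region (default side 60 cost units),
populations log-uniform on [100, 2000] — a heavy-tailed mix of small and
large centers of the same order of magnitude as the nine-center system —
supplies integer-uniform on [1, 5], and planar Euclidean costs. The
generator emulates the *combinatorics* of overlapping catchments, which is
what the conservation laws and the equal-split oracle exercise. It does
not emulate road networks (travel times are symmetric and metric, real
ones are not), spatially autocorrelated population, co-location of supply
with demand, or edge effects at study-area boundaries — so passing
property tests demonstrate the allocation arithmetic, not realism of any
particular empirical system.

The test suite runs the conservation and mass-identity properties on 100
random scenarios of 6–8 centers × 3 facilities and the brute-force
equal-split oracle on 6 × 4 binary instances; these sizes already generate
every qualitative configuration (overlap, no overlap, uncovered units)
while keeping the whole suite fast.

## Diagnostics and equity measures

`conservation_report()` summarizes the mass balance of any run: nominal
demand vs population, total accessibility vs total LOS, the regional PPR
$\sum_j S_j / \sum_i P_i$, the implied PPR $\sum_j S_j / \sum_j D_j$, and
the coverage counts $K_i$ (facilities reaching center $i$ — the
multiplicity with which a center is double-counted under raw binary
weights). `inflation_factors()` takes an unadjusted and a balanced run on
the same scenario and reports per-facility demand ratios
$D_j / D^*_j$ and per-center accessibility ratios $A_i / A^*_i$; the
demand ratio is defined by symmetry with the accessibility ratio — both
are dimensionless and reduce to 1 when catchments do not overlap — and the
$K_i$ counts are reported alongside because either can be read as "how
inflated". Zero denominators yield `NA`, never infinities.

`disparity()` supports equity analysis on balanced results (it accepts any
result, but only balanced ones conserve the totals that make it
interpretable): the equitable share $\bar{L} = \sum_j L^*_j / N$ is each
center's share of the system's service under perfectly even allocation,
and the disparity index $A_i - \bar{L}$ is positive where a center
receives more than that share. Because balanced runs satisfy
$\sum_i A^*_i = \sum_j L^*_j$, the mean disparity is exactly 0 (asserted
to $10^{-12}$). The spatial access ratio $A_i / \mathrm{mean}(A)$ is
provided as a scale-free alternative for comparison with
selection-weighted workflows.

## Known limitations

* No network routing: travel-time matrices are inputs (or planar Euclidean
  for synthetic work). No geocoding, no choropleth mapping, no spatial
  autocorrelation statistics.
* The three-step variant beyond the selection-weight form given here
  (e.g. full probabilistic choice models) is out of scope, as are
  kernel-density, commuter-based and multi-modal extensions.
* Slack factors are user inputs; calibrating them from observed flows or
  expert opinion is left to the analyst.
* Demand is *potential* interaction. Even the balanced method's conserved
  totals describe propensity under proportional sorting, not realized
  utilization.
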