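---
title: "Modelling deforestation, Forest-Code scenarios and carbon with forestca"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling deforestation, Forest-Code scenarios and carbon with forestca}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forestca)
```

## The modelling problem

`forestca` projects categorical land-cover change on a raster landscape and
accounts for the carbon consequences. Its intended use case is the policy
question behind Brazil's 2012 Forest Code revision: the law changed how the
protected riparian strip (the "area of permanent preservation", APP) along
watercourses is delimited — measured from the *regular* (minimum) channel
rather than from the *maximum water level* — which strips protection from
floodplains. The package lets you calibrate a land-change model on two dated
maps, then simulate a baseline (historical behavior) against
full-compliance scenarios under the 1965 and 2012 delimitation rules, and
compare forest loss and committed carbon emissions.

Three transitions are modelled: deforestation (forest to deforested),
regeneration (deforested to secondary vegetation), and cutting of secondary
vegetation. Water, natural non-forest and urban cells never change state.
One simulation iteration is one year.

## Model components and assumptions

### Weights of evidence (where change happens)

For each transition, region and evidence-layer bin the positive weight

$$W^+(B) = \ln \frac{P(B \mid T)}{P(B \mid \lnot T)}$$

is computed over the cells eligible for the transition at the start of the
calibration window, and a cell's transition probability combines its bins
additively on the log-odds scale:
$\operatorname{logit}(P) = \operatorname{logit}(\pi) + \sum_i W_i^+$.
This is the standard Bonham-Carter formulation and assumes the evidence
layers are conditionally independent given the transition; the package does
not test that assumption (layers are declared independent by the user).
Degenerate bins — no eligible cells, or a transition never observed — get
weight 0, i.e. "no information", which keeps every posterior finite. With
two binary layers and exactly independent counts the posterior reproduces
the exhaustive contingency-table Bayes estimate to numerical precision; the
test suite asserts this at $10^{-10}$.

Continuous variables are binned by user-supplied breaks or, by default, by
10 quantile bins; variables with at most 25 distinct integer values are
treated as categorical. Weights depend only on bin contents, not on the
order breaks are supplied in.

### Transition rates (how much change happens)

Rates are estimated per region from the empirical transition matrix of the
calibration window. The default annualization takes the matrix root of the
period matrix over the three dynamic classes,
$A = P^{1/\Delta t}$ (by eigendecomposition), because the three transitions
chain: over a five-year window a cell can be cleared and regrow, and naive
per-transition endpoint fractions systematically understate the annual flows
(by roughly 10–30% at the default synthetic rates). For a class that only
loses cells the matrix root reduces exactly to the compound-survival form
$1 - (1-f)^{1/\Delta t}$, which is also available as `method = "survival"`.
When the empirical matrix has no admissible real root (complex or
substantially negative entries, possible in tiny degenerate samples) the
estimator falls back to compound survival; tiny negative entries caused by
sampling noise on structurally-zero flows are clamped to zero and the rows
renormalized.

### Allocation (the cellular automaton)

Each year, each region's cell demand is `rate × current source count`,
rounded to the nearest integer with the fractional residue carried to the
next year so no systematic bias accumulates. Demand is placed by two
operators:

* **expander** — a share `expander_fraction` of demand is drawn from source
  cells 8-adjacent to existing target-class cells;
* **patcher** — the rest seeds new patches whose sizes are lognormal around
  the region's mean patch size (clipped to ≥ 1 cell), grown by repeatedly
  adding the neighbor that maximizes posterior probability plus
  `isometry × (converted neighbors)/8`.

Candidates come from a pool pruned to the top `demand × pruning_factor`
cells by posterior probability (default 10), sampled probability-weighted.
Patch geometry (mean size, variance, expander fraction) is estimated during
calibration from the connected components of observed change. Within a year
the three transitions are applied in the fixed order clearing →
secondary-cutting → regeneration, and eligibility is frozen at the
year-start state, so a cell undergoes at most one transition per year; this
synchronous update is what makes the carbon ledger identity exact and avoids
same-year clear-then-regrow artifacts. If demand exceeds the eligible
candidates, all candidates convert and the shortfall is logged on the state.

Regeneration is nullified on urban-masked cells, mirroring the observation
that occupied riverside towns do not regrow.

### Roads

The road builder extends the network each year toward targets sampled from
the attractiveness surface (reciprocal friction; roads and rivers attract,
protected areas and slopes above 20% repel, weights configurable), along
least-cost paths on the 8-connected lattice (igraph), within an annual
kilometre budget. The rate feedback is
`rate' = rate × (1 + β × new_km/network_km)` clipped to [0, 1], with β = 1
by default; the multiplicative relative-increment form is a documented
reconstruction (the source literature's exact equation is not public), so β
is exposed as a tunable. Simulations derive their random streams from the
user seed only — scenario rules are the *only* difference between scenario
runs at a given seed (common random numbers), which sharpens paired
comparisons.

### Scenarios, APPs and leakage

Buffer widths follow the statutory width classes (<30 m → 30 m, 30–50 → 50,
50–200 → 100, 200–600 → 200, >600 m → 500 m), rasterized outward from the
chosen reference edge: the regular channel under the 2012 Code, the
floodplain edge (maximum water level) under the 1965 Code — so the 1965 APP
always contains the 2012 APP when floodplains are wider than channels. The
sub-30 m class uses a single 30-m buffer, the finest width representable at
the working resolution. Region precedence when assembling the map is
CU > IR > APP (with the APP2008 carve-out under the 2012 Code) > IL > RB >
IA; the APP overrides everything except conservation units and the
road-influence zone.

In the 1965 scenario the APP's gross deforestation and secondary-cutting
rates are zeroed and the displaced annual cell demand is redistributed as
increments to the *net secondary-cutting* rates of the receiving regions,
proportional to their secondary-vegetation source areas (the "adjacent
areas" of the leakage narrative are not given a formula anywhere; area
proportionality is this package's documented choice). The transfer conserves
total first-year gross demand by construction. In the 2012 scenario
secondary cutting remains permitted in APP2008 — the minimal-restoration
assumption — and no leakage is applied by default (the flag is exposed).
APP2008 restoration-width gradation by property size is deliberately not
modelled.

### Carbon accounting

Committed, instantaneous accounting: clearing a forest cell emits
`biomass × 0.485` (the carbon fraction of dry forest biomass) for its full
area in the clearing year; cutting secondary vegetation of age *a* emits
`0.45 × g × a`, where *g* is the secondary biomass growth rate in
Mg ha⁻¹ yr⁻¹. *g* has no canonical value in this pipeline's sources (it is
cited from pasture-regrowth field studies); it defaults to 10 Mg/ha/yr and
every package guarantee (ledger identity, orderings, recovery) is
independent of its value. Secondary vegetation accumulates carbon linearly
with age, uncapped by default (a cap is configurable; over a 13-year horizon
ages stay small). Secondary vegetation present in the initial map is
assigned age 5, new regrowth starts at age 1. Uptake is netted against gross
emission in the same year. The ledger identity
`stock(t) − stock(t+1) = net(t+1)` holds exactly because both sides are
computed from the same cellwise densities.

### Validation

Fuzzy similarity compares the two *change* maps (cells whose class changed,
labelled by the from-to pair): a changed cell scores 1 if a matching change
lies within the k×k window (constant/crisp decay; an exponential
distance-decay variant is available behind a flag), the directional score is
the mean, and the reported value per window is the minimum of the two
directions. The score is 1 on identical change maps and non-decreasing in
window size. Quantitative validation reports per-class signed area
differences (real − simulated) and percentages of the real areas.

## The synthetic study area

No rasters from the original study region are publicly deposited, so the
generator is a first-class module. It emulates a 30-m-resolution frontier
landscape: two sinuous rivers spanning the statutory width classes (a 20-m
stream, and a 150-m river whose maximum-water-level extent is three times
the channel — floodplains strictly wider than channels), a highway entering
from the southern edge, initial clearing (12% of land) clustered near roads
and rivers via a distance-decay score plus a smoothed random field, 15% of
the area in two protected blobs far from roads, a small urban nucleus where
the road approaches the river, terrain from smoothed Gaussian noise, and
forest biomass around 350 ± 60 Mg/ha. True annual rates default to 0.02
(deforestation), 0.08 (regeneration) and 0.10 (secondary cutting). The
"true" forward model (`evolve_landscape()`) draws binomial counts per region
and allocates them with multiplicative distance-decay preference — the same
conditional-independence family the calibrator assumes, which makes
parameter-recovery tests well-posed.

What the generator does **not** emulate: realistic hydraulics or terrain,
seasonality, property boundaries, multi-class competition, or spatially
varying true rates. Passing tests therefore demonstrate the *estimators and
bookkeeping* are correct under the model's own assumptions, not that the
model transfers to any particular real landscape.

Deliberate scale choices: the default study area is 200×200 cells (6 km ×
6 km), with the road-influence region defined by a 900-m distance at that
scale (the real region's analogue is tens of kilometres). Test problem
sizes are the package's choices for statistical power: parameter recovery
uses a 300×300 grid, where the rarest source class gives the annualized-rate
estimator a 2–3% sampling sd, leaving the 10% recovery check a >3σ margin;
the three-scenario ordering experiment uses five seeds at 120×120 over 13
years.

## Numerical choices and degenerate inputs

* Distances are quasi-Euclidean two-pass chamfer (1/√2) transforms; buffers
  and dilations reuse them, so buffer edges are accurate to about one cell.
* Rasterized on-disk format is the 6-line-header ASCII grid (lossless for
  codes and georeference, and diff-able); rivers/roads are GeoJSON
  LineStrings.
* Zero-cell regions and absent transitions yield rate 0 with a warning,
  never NaN; posteriors are kept in (0,1) by the weight-0 convention.
* Demand rounding residues accumulate; allocation shortfalls are logged, not
  silently dropped; leaked demand with no receiving secondary area is
  dropped with a loud warning.
* All stochastic stages take explicit seeds; stage seeds are derived from
  the master seed by a stable hash, so every stage is independently
  reproducible and nothing depends on global RNG state.

## Known limitations

Single-cell transitions only (no sub-annual dynamics); conditional
independence of evidence layers is assumed, not tested; the road-feedback
equation and the patcher/expander internals are documented reconstructions
of platform conventions rather than published formulas; leakage
apportionment ignores spatial adjacency; carbon excludes soil, necromass
dynamics and non-CO₂ gases. The headline quantities of the original
application (thousands of km² of projected clearing) required the real
regional rasters and are out of desk-scale reach; the package's guarantees
are the in-package arithmetic and the property-based checks described above.
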