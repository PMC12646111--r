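---
title: "Methods: reservoir emission accounting, calibration, explanation and planning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reservoir emission accounting, calibration, explanation and planning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(resghg)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, what the
synthetic data generator does and does not emulate, and the numerical and
design choices made where the methodology leaves them open.

## The emission model

Reservoirs emit greenhouse gases along four pathways: diffusive CO₂ from
the water surface, diffusive CH₄, ebullitive (bubbling) CH₄ from shallow
sediments, and CH₄ degassed just downstream of the dam as deep, gas-rich
water depressurises through outlets and turbines.  All fluxes in this
package are areal, in gCO₂e/m²/yr — the unit of the shipped
emission-factor table — and the mass identity is exact by construction:
g/m²/yr × 10⁶ m²/km² = 1 t/km²/yr, so `total_mass = total_areal × area_km2`
with no rounding.

Two estimation routes are implemented behind one interface:

* **Tier 1** (`tier1_gross_profile`): one constant flux per (climate zone,
  pathway) cell.  The shipped table (`load_ef_table()`) encodes the
  published global factors for the six-zone stratification together with
  country-recalibrated variants; absent cells are represented as missing
  and looking them up raises a typed error rather than silently
  substituting.  Degassing requires a deep intake, which irrigation
  reservoirs usually lack; the `include_degassing_for_irrigation` flag
  keeps the inclusive accounting by default and zeroes the pathway when
  turned off.
* **Empirical pathway model** (`predict_empirical_profile`): per pathway,
  `flux = linkinv(intercept + Σ coefᵢ·featureᵢ)` with identity or log10
  link, over reservoir and catchment features (prefix `res.`/`cat.`
  disambiguates shared names such as `area`).  Published regression
  coefficients for this class of model are licensed artefacts that the
  package deliberately does not hard-code: the coefficients are user
  configuration, and the shipped defaults come from the synthetic truth
  generator.  CH₄ pathways are multiplied by a required `gwp_ch4`
  CO₂-equivalence factor — there is no silent default, because the right
  value depends on the integration horizon the user intends.

Negative identity-link predictions are clamped to zero with a recorded
warning: gross fluxes are non-negative by definition, and a clamp signals
that the configured regression is being extrapolated.

### Net anthropogenic emissions

Gross surface fluxes overstate a reservoir's atmospheric impact: the
pre-impoundment landscape had its own GHG balance (tropical forests on
mineral soils are net sinks, so flooding them *adds* emissions), and part
of the gross flux is driven by unrelated anthropogenic nutrient and
organic loading.  The model path computes

```
net_areal = gross_total × (1 − uas_fraction) × lifetime_multiplier
            − displaced_areal − pre_impoundment_areal
```

where the lifetime-integration multiplier and displaced-emission term
default to neutral (1 and 0) — the methodology names these balances
without specifying them, so they are exposed as explicit knobs rather than
buried assumptions.  The Tier 1 path uses the linear net relation
`F_net = (net_CO2·F_CO2 + net_CH4·F_CH4) × (1 + R_downstream)`.  The
relation is printed in per-day units in the literature; because it is
scale-invariant we apply it directly in per-year units and provide
`flux_per_day()`/`flux_per_year()` (×/÷ 365.25) for reporting parity.
`F_CH4` defaults to the sum of all three CH₄ pathways, with a switch for
surface-only aggregation, since the published calibration does not state
which aggregation its coefficients assume.

A structural point discovered while implementing the calibration
(`calibrate_net_params`): the triple `(net_CO2, net_CH4, R_downstream)` is
not jointly identifiable from paired gross/net data — only the products
`net·(1+R)` are, because any rescaling of `(1+R)` can be absorbed by the
proportions.  We therefore profile `R_downstream` over a user grid, score
each candidate by the residual sum of squares of the box-constrained
(|net| ≤ 1) least-squares fit, and break ties toward the smallest ratio.
The *fitted relation* is unique even though the triple is not; the
constraint makes large ratios identifiable only when the implied
proportions would exceed one.

### Emission intensity

`emission_intensity` is tCO₂e/yr over GWh/yr, i.e. g/kWh.  Run-of-river
assets have no impounded surface, so they carry a constant biogenic
intensity (3 gCO₂e/kWh by default) regardless of mass; the lifecycle
variant adds a constant 19 gCO₂e/kWh for infrastructure and supply-chain
emissions, applied identically to storage and run-of-river hydropower
because reported ranges for the two overlap widely.

## Emission-factor calibration

Country-specific Tier 1 factors are refit by ordinary least squares of the
per-reservoir pathway fluxes on climate-zone indicator variables with no
global intercept.  Because the indicators are disjoint, the OLS solution
is algebraically the per-zone arithmetic mean — the package asserts this
identity on random data rather than trusting it.  Zones absent from the
fleet yield absent cells; per-cell sample counts are carried so a rendered
table can flag thin strata.

Uncertainty comes from a nonparametric bootstrap: reservoirs are resampled
with replacement (1000 resamples by default), the zone fit repeated, and
the margin reported as half the width of the percentile 95% interval.  The
percentile method was chosen over a normal approximation because the
margin definition only requires interval endpoints and the resampled means
can be skewed for small zones; a `method = "normal"` switch preserves the
alternative.  Two degenerate regimes are handled explicitly: a zone with
zero within-zone variance gets margin 0, and a zone absent from more than
half of the resamples would be flagged unreliable.  (For a zone with at
least one reservoir the absence probability is at most e⁻¹ ≈ 0.37, so the
flag is a guard for pathological inputs rather than an expected path; a
single-reservoir zone instead shows up as `n = 1` with a degenerate,
zero-width interval, which is why fitted tables carry `n`.)

## Delineation

The raster core re-implements, on local grids, the delineation chain that
large-scale tooling runs on global datasets: D8 steepest-descent flow
directions (ties and flats resolved by the fixed neighbour order N, NE, E,
SE, S, SW, W, NW), Kahn-traversal flow accumulation, dam snapping to the
nearest river cell (accumulation ≥ threshold; ties by higher accumulation,
then row-major order), reverse-BFS local catchments, full-supply-level
flooding and land-cover extraction of existing water bodies.  Flooding
uses 4-connectivity (a diagonal water connection across two dry cells is
physically dubious at these resolutions) while routing uses the
8-neighbour stencil; grid coordinates are (row, col), 1-based,
cell-centre registered.  The full supply level defaults to the dam-base
elevation plus dam height minus the freeboard between supply level and
crest; a supply level below the base yields an empty mask plus a warning
rather than an error, so batch runs can skip infeasible sites.

Upstream drainage areas beyond the local catchment are compiled on an
abstract sub-basin tree with Pfafstetter codes.  Codes are generated by
the standard recursive scheme — main stem by largest drained area, the
four largest tributaries get even digits in upstream order, interbasins
odd digits — which guarantees the property the filter relies on: codes
never decrease in the upstream direction.  Two points the methodology
leaves open are resolved as follows: codes of unequal length are compared
hierarchically at the first differing digit (the generated codes are
prefix-free, so the comparison is total), and the region of interest is
the coarsest code prefix of the dam's sub-basin whose member set is closed
under upstream drainage.  Both choices are validated against an
exhaustive ancestor search on random basin trees.

Only the ESRI ASCII grid format is supported for raster I/O.  It is a
trivially inspectable text format, sufficient for the grid sizes this
package targets, and keeps the dependency footprint to base R.

## Surrogate models and explanations

Two gradient-boosted regression-tree surrogates (one for net areal CO₂,
one for CH₄) emulate the emission model from its input–output pairs.
Hyperparameters — learning rate, tree depth, minimum child weight,
feature/bagging fractions, L1/L2 penalties — are drawn by seeded random
search (50 trials by default) and scored by out-of-fold RMSE under 5-fold
cross-validation with early stopping (1000 round cap, 50-round patience);
the final model refits all data with the best parameters and the mean
early-stopped round count.  Reported metrics are out-of-fold:
RRMSE = 100·RMSE/mean(y), RMAE = 100·MAE/mean(|y|) (denominators are our
definition, stated here because the literature rarely defines them) and
R²; a constant target makes R² undefined and it is reported as `NA`.
Training is deterministic for a fixed seed with single-threaded tree
construction.

Instance-level explanations use breakdown attributions: the intercept is
the mean prediction over a background sample; features are fixed one at a
time to the instance's values across the whole background; each
contribution is the change in the mean prediction; the identity
`intercept + Σ contributions = prediction` holds exactly by telescoping.
The fixing order is greedy by decreasing single-feature effect magnitude —
the published breakdown method leaves the ordering open, and for additive
models the attributions are provably order-independent, which the tests
exploit as a closed-form oracle.  Interaction attributions are out of
scope in this version.  The background defaults to the full training
matrix; a seeded subsample is available for speed.

Model-level importances are permutation-based: the mean (and sd) RMSE
increase over 10 shuffles of each column.  A feature the fitted trees
never split on leaves predictions bit-identical, so its importance is
exactly zero — a useful sanity check that the tests assert.  Attribution
matrices are embedded by column-centred PCA (SVD); driver categories come
from k-means on the scores (3 by default).  The categories are a reading
aid for grouping similar driver profiles, not a statistical claim, and the
arrows exported for plotting are the loadings of the three globally most
important features.

## Portfolio planning

The planner selects subsets of candidate dams on a river network
represented as a rooted tree in which nodes are contiguous dam-free river
regions and dams are directed edges from the downstream to the upstream
region (`to_tree` performs the line-graph-style transform and merges
dam-free stretches; a dam with no upstream river node gets a synthesised
headwater region).  Objectives are declarative: each combines a per-asset
metric, a sense (max/min) and an aggregation — sums for hydropower and
firm power, means or sums for emissions and land losses.  Mean-aggregated
objectives are carried through the dynamic program as (sum, count) pairs
so merging stays exact; the mean of the empty portfolio is defined as 0.
Firm power is the 5th percentile of the generation series under the
linear-interpolation convention (R quantile type 7), annualised by the
caller.

The ε-approximate frontier is computed bottom-up: each subtree carries a
set of (portfolio, accumulator) states; children merge by accumulator
addition; after every merge, states are pruned.  Pruning is exact
dominance (within equal-count groups when mean objectives are present,
because states with different counts are incomparable before the
denominator is known) plus, for ε > 0, a grid on the normalised
accumulators whose cell width divides ε/2 by the worst-case number of
prune events on any root-leaf accumulation path.  The root set is then
realised exactly (vectors recomputed from the portfolios, never from the
rounded accumulators), filtered for dominance, and thinned greedily so no
kept point is within ε/2 (normalised, per objective) of an earlier kept
point.  The two halves of the budget compose additively, so every
feasible portfolio is ε-dominated by some returned point; at ε = 0 the
result is the exact Pareto set, which the tests verify against exhaustive
enumeration.  Normalisation ranges come from single-asset extrema and are
recorded in the result for reproducibility.

The frontier dimension drives the cost: river networks are deep and
chain-like, so dominance pruning is weak in many dimensions.  The
demonstration pipeline therefore optimises the canonical two-objective
energy-versus-emissions trade-off and reports firm power, intensities and
land losses along the frontier; the five-objective specification remains
available and is exercised in the tests on smaller networks.  The built
scenario forces existing assets into every portfolio; comparing built and
not-built frontiers quantifies the lost opportunity of planning without
emission criteria.

## The synthetic generator

`synth_landscape` builds a stylised landscape whose *statistical*
structure matches what the framework assumes: a smoothed random-field
elevation model (plane tilted toward a single boundary outlet plus
Gaussian hills, ~0–1200 m relief), hydrologically conditioned by
priority-flood filling so the D8 network has exactly one outlet;
temperature falling with elevation at a fixed lapse rate; runoff rising
with elevation and higher on the moist half; population density and
cropland concentrated in the warm lowland; forest probability increasing
with elevation and moisture; and the six climate-zone labels assigned by
elevation tercile × dry/moist half.  `synth_fleet` places dams on
high-accumulation river cells (60 by default, 500 m cells on a 48×48
grid, dam heights 25–70 m), delineates every reservoir and catchment
through the package's own delineation code, and derives the dam tree from
the drainage paths.  `synth_emission_truth` attaches a linear
(identity-link) emission law with the canonical driver signs — CH₄
falling with mean depth, rising with temperature and catchment area; CO₂
rising with impounded forest fraction and temperature — plus a per-zone
level shift so calibration has a recoverable target, and emits the
generating law as an `empirical_model_config`, making zero-noise
self-consistency an exact test.  A log10-link variant of the law is the
natural stress test and the config supports it.  `synth_generation`
produces 38 years of weekly energy from the hydropower formula
P = ρ·g·η·Q·H with seasonal-sinusoid flows and head proportional to mean
depth.

Two direct generators bypass the raster pipeline where it would add cost
but no information: `synth_calibration_samples` (zone means + Gaussian
noise — the minimal process under which zone regression provably targets
the injected means; defaults n = 300, sd = 80 gCO₂e/m²/yr over three
warm-climate zones) and `synth_surrogate_data` (feature draws from
realistic marginals with a smooth known law, noise sd 30 gCO₂e/m²/yr at
n = 500).

What the generator does *not* emulate — and hence what green tests do not
show about real data: real hypsometry and river geometry (reservoir
area-to-catchment ratios remain larger than typical real hydropower
sites, so absolute emission intensities at the high end exceed national
figures), soil carbon and trophic status as emission drivers, correlated
measurement error, operating rules and storage dynamics in the generation
series, and any real country's fleet composition.  Headline numbers from
national case studies are therefore not reproduction targets; the
acceptance suite instead checks printed constants exactly and everything
else by property and recovery.

## Problem sizes and numerics

The shipped tests and the acceptance script use: 100 random grids up to
30×30 for the delineation oracles; 100 random trees with up to 12 assets
(2¹² enumeration) for planner exactness; 50 simulated 300-reservoir
fleets × 1000 bootstrap resamples for interval coverage; surrogate
training at n = 500 with a 10-trial search; and the full 60-dam pipeline
end to end.  These sizes were chosen so the whole suite exercises every
code path in a few minutes on one core while keeping each statistical
check adequately powered.

Numerical conventions, in one place: flux totals compare at 1e-9 relative
tolerance; the DP prunes on strict dominance with exact arithmetic and
realises frontier vectors from portfolios, never from rounded
accumulators; quantiles use R type 7 everywhere; k-means uses 10 restarts
under a fixed seed; bootstrap and permutation draws derive from explicit
seeds, and a fixed seed reproduces every result bit-for-bit.

## Known limitations

Static annual fluxes (no stratification, drawdown or seasonal dynamics);
N₂O is out of scope; the empirical model ships without published
regression coefficients by design; box-constrained net-parameter fits
project coordinate-wise rather than solving the constrained least-squares
problem exactly (adequate when the fit lies near the box); the planner's
state space grows quickly with the number of objectives on deep networks;
and GeoTIFF rasters are not read — convert to ESRI ASCII grids first.
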