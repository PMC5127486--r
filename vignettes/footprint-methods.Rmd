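---
title: "Mapping cumulative human pressure: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping cumulative human pressure: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(footprintr)
```

## The model

The human footprint is a cumulative-pressure index: eight gridded human
pressures are each standardized onto a bounded scale that reflects their
relative intensity, then summed cell by cell on a common equal-area 1-km
grid. A cell's score ranges from 0 (no mapped pressure) to 50. The eight
pressures and their weights:

| pressure | score | rule |
|---|---|---|
| built environments | 0, 10 | calibrated night-lights DN >= 20 |
| population density | 0–10 | `min(10, 3.333 * log10(density + 1))`, 10 at >= 1000 people/km² |
| night-time lights | 0–10 | 10 equal-count DN bins from the reference year |
| croplands | 0, 7 | binary crop mask, excluded on built cells |
| pasture | 0–4 | `4 * percent_cover / 100`, excluded on built or cropped cells |
| roads | 0–8 | 8 within 0.5 km; access score 4 decaying exponentially to 15 km |
| railways | 0, 8 | 8 within 0.5 km, no access decay |
| navigable waterways | 0–4 | access score 4 at the water edge decaying to 15 km |

Pressures are deliberately not mutually exclusive — a city cell is
simultaneously built, lit, populated and roaded — with two exceptions
enforced as a land-use hierarchy: a built cell carries no crop or pasture
score, and a cropped cell carries no pasture score. Under that hierarchy the
largest attainable sum is 10 + 10 + 10 + 8 + 8 + 4 = 50 (a built cell gains
more than a cropped one); with the hierarchy disabled the arithmetic maximum
would be 61. `max_possible_score()` computes both by enumerating the
2³ exclusion states, and `combine_pressures()` *asserts* rather than clamps
the bound, so a misconfigured scheme fails loudly instead of silently
distorting the map.

### Population density

Pressure is assumed to grow logarithmically with density and saturate:
cells at or above 1000 people/km² score 10, below that
`3.333 * log10(density + 1)`. Base-10 logarithms make the curve continuous
at the saturation point (`3.333 * log10(1001) = 10.0004`, within 0.001 of
the plateau); we cap the sub-saturation branch at 10 so the layer never
exceeds its ceiling. Coarser census grids are brought to the analysis
resolution with `bilinear_resample()`, which interpolates between cell
centres, extrapolates linearly at the margins (so any affine surface is
reproduced exactly), and renormalises around nodata support.

### Night-time lights

Satellite night-light composites from different years are not directly
comparable, so raw digital numbers (DN, 0–63) are first passed through a
quadratic intercalibration fitted by least squares on a reference region
assumed unchanged between vintages (`fit_dn_calibration()`); the default is
the identity. DN of 6 or less are zeroed before calibration — the quadratic
badly distorts very low DN — and the same floor excludes those cells from
binning. The reference year's above-floor DN are then split into 10
equal-count bins scored 1–10 (`compute_light_bins()`, upper-bound
thresholds with ties falling to the lower bin), and the *same* thresholds
convert every other vintage so scores are comparable over time. Equal
counts are only attainable up to ties: on heavily tied (integer) DN the
thresholds are still well defined but bins are unequal, and duplicated
thresholds raise a warning. Bright cells (DN >= 20 after calibration) are
additionally classed as built; the built threshold is configurable because
the sources give both "greater than 20" and "equal to or above 20" — we use
>= 20.

### Linear infrastructure and the decay kernel

Roads exert a direct pressure of 8 within 0.5 km of the line and an access
pressure — people reaching the landscape from the road — of 4 at 0.5 km
decaying exponentially to 15 km. A pure exponential never reaches zero, so
the kernel is truncated: the decay rate is set so the kernel value hits a
floor (default 0.25 = 4/16) exactly at 15 km, and anything below the floor
is zeroed. At exactly 0.5 km the access value (4) applies; the direct band
is the open interval below it. Railways carry only the direct band:
passengers rarely disembark between stations, so rails do not open the
landscape around them. Distances are exact centre-to-centre Euclidean
distances on the equal-area grid, computed with a separable two-pass
squared-distance transform and cross-checked in the tests against an
all-pairs brute-force oracle.

### Navigable waterways

Water bodies act as conduits like roads, with navigability decided by
hydraulic geometry and settlement evidence:

* Channel geometry follows empirical power laws: width `8.1 Q^0.58` m,
  velocity `4.0 Q^0.6 / width` m/s, cross-section `Q / velocity`, and, for a
  parabolic channel, depth `1.5 area / width`. The chain collapses to
  `depth = 0.375 Q^0.4`, so the 2-m draft limit is a single discharge
  threshold, `(2/0.375)^2.5 ≈ 65.7` m³/s — verified in the tests by
  bisection on the full equation chain.
* A river reach is seeded navigable if it is deeper than 2 m *and* shows a
  settlement signal (night-lights DN >= 6 within 4 km of its cells), or if
  it is contiguous with navigable coast or lake shore. Navigability then
  propagates along the reach graph through deep reaches only, for a
  cumulative 80 km counted over both the seed and the entered reaches (a
  chain of 10-km deep reaches seeded at one end yields exactly eight
  navigable reaches); shallow reaches block propagation. The DN threshold
  is >= 6 everywhere; the sources vary between "> 6", ">= 6" and "> 4", so
  it is a scheme parameter.
* Coasts are navigable for 80 km either direction of a settlement signal,
  with distance accumulated *along* the coast (shortest path over
  8-connected coast cells with 1/√2-cell steps), never as a straight line
  across bays; straight-line search is available as an option. The 80-km
  range approximates a day's return boat trip. Large lakes are treated
  exactly like marine coasts; which lakes qualify is input data (the lake
  mask), not code.
* The access kernel for navigable water has no direct band: the plateau of
  4 covers the water cells and their 8-neighbourhood (cell centres within
  √2 cells — the raster rendering of "adjacent to the water body"), then
  decays exponentially to 15 km like the road kernel.

## Validation statistics

A footprint map is assessed against plots whose pressures were scored by a
human interpreter from high-resolution imagery. Plots flagged "uncertain"
are discarded. Both score sets are normalized to 0–1 — the footprint by
`max_possible_score()` (50), the visual scores by the maximum of the
interpretation key (a user-supplied constant, since the key is external to
the map) — and compared with:

* **RMSE** of the normalized pairs.
* **Threshold-match kappa**: two scores agree when within 0.20 of one
  another on the 0–1 scale ("within 20%" is absolute difference, not
  relative). Chance agreement is the match rate over all ordered pairs of
  one vector against the other — the permutation expectation of the observed
  rate — giving `kappa = (p_o - p_e) / (1 - p_e)`. The published statistic's
  exact categorical construction is not recoverable from its description, so
  a classical Cohen's kappa on 0.2-wide score bins is reported alongside
  (`binned_kappa()`) for sensitivity.
* **Agreement counts**: plots where the map over- or under-scores the visual
  value by more than the threshold, and the remainder within it.
* **Stratified RMSE** per biome (or any stratum label) for strata holding at
  least 100 plots; smaller strata are omitted with a notice.

Kappa is reported at the working threshold and at ±0.05 around it; on all
data we have examined it rises with the threshold, but that monotonicity is
an empirical regularity, not a theorem.

## The synthetic landscape

`make_landscape()` builds a deterministic toy world exercising every rule:
a bright urban core (road–rail crossing, dense population, DN ≥ 20) so the
score stack reaches past 40; dim rural lights; a crop field and a pasture
gradient overlapping the exclusion hierarchy; a west-edge coast with one lit
settlement; an inland lake; a stream chain whose discharges are drawn
log-uniformly on [1, 1000] m³/s and redrawn (deterministically, under the
seed) until both sides of the 65.7 m³/s depth frontier occur; and an
uninhabited wilderness block kept more than 15 km from every access kernel
so the footprint contains exactly-zero cells, as real landscapes do. A small
nodata patch exercises mask propagation. Bundles are bit-for-bit
reproducible per seed, and the round-trip contract (scores in [0, 50], at
least one cell above 40 and one at 0) is guaranteed at the default 64-cell
size; at the 32-cell minimum the kernels overlap the whole extent and only
the score-range contract survives.

`make_validation_table()` samples plots uniformly over data cells and sets
visual scores to the normalized footprint plus Gaussian noise truncated to
[0, 1] — the simplest error model whose recovery is predictable: with zero
noise RMSE is 0 and kappa 1; with noise the recovered RMSE converges to the
truncated noise sd (slightly below the injected sd, since many footprint
values sit near the scale floor where truncation halves the error). The
tests compare the recovered RMSE against a fresh Monte-Carlo expectation
computed from the same footprint distribution rather than against the raw
sd.

What the generator does *not* emulate: sensor artefacts of night-light
composites (over-glow, gas flares), classification error in crop masks,
spatial autocorrelation of interpreter error, or realistic hydrography.
Passing tests demonstrate the algorithms implement their stated rules, not
that the pressure weights are ecologically correct for any particular
region.

## Numerical and I/O choices

* Problem sizes: tests and examples run on 48–64-cell grids (1-km cells) and
  networks up to 50 reaches; every algorithm is exact at any size, and the
  brute-force oracles in the test suite bound the sizes, not the
  implementation.
* Grids are plain matrices with an explicit nodata mask; the package never
  reprojects and requires all inputs co-registered (same shape, cell size,
  origin), failing otherwise. Nodata cells are excluded as distance sources
  and never receive scores.
* Raster I/O: Esri ASCII grid (self-describing text) and single-band
  float32 TIFF with a JSON sidecar carrying cell size, origin, nodata value
  and the affine packing used to store arbitrary ranges in [0, 1] floats.
  GeoJSON lines/polygons are rasterized by segment supercover /
  centre-intersection.
* Ties at a bin threshold go to the lower bin; quantile thresholds use the
  inverse-ECDF definition (type 1), matching a sort-and-slice oracle
  exactly.
* Degenerate inputs fail loudly: empty feature masks (distance undefined),
  all-tied DN (degenerate thresholds), fewer above-floor cells than bins,
  discharges <= 0, misregistered grids, out-of-range scores.
* Empty road/rail masks are a warning plus an all-zero layer, since a
  roadless landscape is a legitimate study area.

## Known limitations

* The intercalibration coefficients used for the published composites were
  never released; the default here is the identity, and any reference-region
  pair table can be fitted instead.
* Spreadsheet validation tables must be exported to CSV/TSV first.
* The along-coast traversal treats the coast as 8-connected cell chains; a
  coast digitized wider than one cell shortens along-coast distances
  slightly.
* Global-scale (10⁸-cell) processing is out of scope: everything is held in
  memory.
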