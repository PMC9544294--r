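---
title: "Methods: exposure of marine biodiversity to extreme warming rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exposure of marine biodiversity to extreme warming rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oceanexposure)
```

## The exposure model

The package asks a rate question, not a magnitude question: will the speed
of 21st-century ocean warming exceed anything the resident biota has
experienced since the last deglaciation? The unit of comparison is the
signal-to-noise ratio of the centennial SST trend,

$$\mathrm{SNR} = \frac{|b / (G/100)|}{\sigma},$$

where $b$ is the per-cell OLS trend (°C/yr) within a 100-year window flagged
as an *extreme century*, $\sigma$ is the standard deviation of the OLS
residuals in that window (denominator $n-2$), and $G$ is the era-mean global
warming rate (°C/century) over the era's extreme windows. Dividing by
$G/100$ is *pattern scaling*: it expresses the local trend per degree of
global warming, so a deglacial era forced at 0.4 °C/century and a scenario
era forced at 1.5 °C/century become comparable. The package computes SNR
**after** scaling. The defining equation of SNR and the scaling step admit
either order; scaling first is the only order under which past and future
SNR share units, which is the entire purpose of the comparison, so that
order is fixed here (the unscaled ratio is also reported as `snr_raw`).

An *extreme century* is a 100-year window of the area-weighted global-mean
SST whose OLS rate meets or exceeds a threshold (inclusive). The threshold
is either supplied (0.18 °C/century, the canonical calibration) or computed
by `calibrate_threshold()` as the 95th percentile of a control run's window
rates. Windows slide with a 10-year stride; "century" fixes the length but
not the stride, and decadal stepping balances coverage against the strong
dependence of adjacent windows. Overlapping extreme windows are averaged
without merging. Windows belong to an era by their start year (past: start
≤ 1850; future: 1851 onward, including the historical segment).

## Realm-level comparison

Per biogeographic realm (realms under 3 ocean cells are dropped), the past
and future SNR samples are compared three ways:

* two-sample, two-sided Kolmogorov–Smirnov `D` with the asymptotic p-value
  (realm samples are moderate to large, where the asymptotic form is
  standard), corrected across realms with Benjamini–Yekutieli, which is
  valid under the arbitrary spatial dependence between realm samples;
* the proportional overlap of Gaussian kernel density estimates, the
  regional exposure index (low overlap = high exposure);
* hotspot exceedance: the share of the realm's hotspot cells whose future
  SNR strictly exceeds the realm's 95th percentile of past SNR. "Exceeds"
  is strict; ties at the threshold do not count. A sweep of the percentile
  from 90 to 100 yields the reported sensitivity SD.

Density overlap uses Silverman's rule (`bw.nrd0`) per sample, exact kernel
evaluation on a shared 512-point grid spanning the pooled range padded by
three bandwidths, and trapezoid integration. Tests verify agreement with a
$10^5$-point quadrature to $5\times10^{-3}$. A zero-variance sample falls
back to a bandwidth of $10^{-6}|\bar x| + 10^{-9}$ with a warning. Realms
are classed by area-weighted centroid latitude: |lat| ≤ 50° is
tropical/mid, else high.

## Richness and hotspots

Richness at the fine grid is the count of species with occurrence
probability ≥ τ (τ = 0.4 by default; inclusive, matching the other
thresholds in the chain), after dropping species flagged data-scarce.
Richness is aggregated to the climate grid by block means, and hotspot
cells are those at or above the 95th percentile of global ocean richness.
All percentiles in the package use linear interpolation between order
statistics (type 7), stated to pin down tie behaviour. Sensitivity of the
richness surface to τ is quantified with Warren's I on the thresholded
counts,
$I = 1 - \tfrac12\sum_i(\sqrt{p_i}-\sqrt{q_i})^2$ after normalising each
surface to sum 1.

## Thermal analogues

The past series is delta bias-corrected against the scenario reference over
an overlap window (per-cell constant shift of means). "Upper" temperature
is read as the per-cell **maximum** of annual means within the window —
the conservative literal interpretation, applied identically to the
Holocene-thermal-maximum window (9000–5000 B.P.) and the end-of-century
window (2080–2100). Cell *j* is an admissible analogue of focal cell *i*
when `future_upper(j) <= htm_upper(i) + tol` (tol = 0 by default; a ceiling
constraint, with an optional tolerance for sensitivity work).

Sea distances are shortest paths over a graph whose nodes are ocean cells
and whose edges join 8-neighbours with haversine weights (R = 6371 km);
a diagonal edge requires at least one of the two shared orthogonal
neighbours to be ocean, so paths cannot slip between diagonally adjacent
land cells. Longitude wraps at the dateline; rows do not wrap over the
poles. Grid-constrained paths overestimate true geodesics slightly; all
conclusions rest on relative distances, where the bias cancels. Ties among
equally near analogues break by distance, then lower future temperature,
then row-major cell index, making results order-independent. Required
redistribution rates divide the distance by a 70-year horizon (2020–2090).

## The synthetic world

No global paleoclimate, scenario, species or realm datasets ship with the
package; `generate_world()` builds inputs with the statistical structure
the method assumes, plus analytic ground truth:

* **Signal.** `sst(cell, t) = climatology(lat) + amplification(cell)·G(t) +
  ε(cell, t)`. The climatology is `T_pole + (T_eq − T_pole)cos²(lat)`
  (28 °C to 0 °C by default). `G(t)` is piecewise linear through injected
  abrupt events for the past (defaults patterned on the deglaciation: two
  large abrupt warmings, a mid-Holocene build-up, a slow late cooling),
  linear for scenario futures (0.72 and 1.48 °C/century), zero for the
  control.
* **Noise.** Per-cell AR(1) (φ = 0.4) with stationary SD
  `0.2·(1 + 2·sin⁶(lat))` °C: low and flat through the tropics and
  mid-latitudes, rising steeply poleward, as for real interannual SST
  variability. Cells are independent; no ENSO-like teleconnections.
* **Amplification.** Past events are expressed proportionally to local
  variability times an extra polar factor (`past_polar_snr = 4`, same
  flat-then-steep latitude shape), so past SNR is low and homogeneous in
  the tropics and high and broad at high latitudes — the pattern of
  polar-amplified abrupt deglacial events. Future warming tracks the
  variability profile alone. The consequence the pipeline should detect:
  future rates are unprecedented in the tropics but inside the experienced
  range at high latitudes.
* **Species.** Gaussian occurrence-probability bumps with range centres
  drawn from a tropical-peaked latitude distribution; richness after
  thresholding peaks within ±30°. Because the bumps have unbounded
  support, a threshold of exactly 0 marks every cell present — richness
  maps at τ = 0 are therefore much flatter than at τ ≥ 0.1, and the
  threshold-sensitivity I against τ = 0 is far below what bounded range
  envelopes would give. Comparisons among τ ≥ 0.1 are the informative ones
  here.
* **Geography.** Two one-cell meridional land strips (closable or gapped)
  split the ocean into two basins — closed barriers give disconnected
  components for no-analogue tests; realms are latitude bands within
  basins (contiguous by construction); the EEZ mask is the ocean cells
  within a configurable 8-neighbour distance of land.

Every sub-generator draws from a named stream derived from `master_seed`,
so worlds are bitwise reproducible and independent of call order.

What passing tests on this world do **not** show: skill on real data. The
generator has no ocean dynamics, no spatially correlated noise, no
seasonal cycle, no observational error in species ranges, and its realms
are geometric. It demonstrates that the estimators recover known
parameters and that the pipeline's qualitative conclusions follow from the
assumed structure — not that the structure holds in nature.

### Problem sizes and fixture design

The demo configuration (`demo_world_config()`) is a 10° world with a
2000-year past, a 400-year control and 250-year futures, 150 species on a
2° species grid, and 8 realms; the full pipeline runs in a few seconds,
which keeps the test suite and the acceptance script fast while leaving
every code path exercised. Parameter-recovery checks use a 5° world
(≈ 2500 ocean cells) so that means over cells are tight.

The event-detection check injects five 0.5 °C/century episodes separated
by gaps *shorter than the 100-year window*. This is deliberate: the
detection threshold is by definition the 95th percentile of the control
distribution, so roughly 5% of event-free windows must exceed it by
construction; only a layout in which every window overlaps an episode
makes "no spurious detections" a well-posed requirement. The check then
verifies that each episode is flagged and nothing else is.

## Numerical choices

* Percentiles: type 7 (linear interpolation); thresholds inclusive (≥)
  except exceedance, which is strict (>), because "exceeds" implies it.
* Residual SD: denominator $n-2$ (OLS residual degrees of freedom).
* A window-mean variability below $10^{-12}$ °C (noise-free degenerate)
  sets SNR missing with a warning rather than propagating infinities.
* Area weights: `cos(latitude)` of the cell centre by default; exact
  spherical band areas are available (`area_method = "spherical"`). Both
  are proportional weights.
* Aggregation: a coarse cell is the mean of its non-missing children, and
  missing only when all children are.
* Output tables round to 10 decimal places before writing so that content
  hashes are stable across platforms.

## Limitations

* The sea graph measures grid paths, not geodesics around coastlines;
  distances are upper bounds with resolution-dependent bias.
* The asymptotic KS p-value is approximate for small realms (minimum 3
  cells); an exact variant is not provided.
* NetCDF support covers the classic (CDF-1) format this package writes —
  fixed dimensions, numeric and byte variables — not the general NetCDF-4
  feature set.
* Scenario futures share the past's variability structure; changes in
  variance under forcing are not modelled.
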