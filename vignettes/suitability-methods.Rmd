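---
title: "Envelope-based suitability analysis for export banana: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Envelope-based suitability analysis for export banana: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bananaclim)
```

## The problem

Intensive export banana production occupies a small corner of the
environmental and logistic space available in Latin America and the
Caribbean. Given a gridded map of where plantations are (hectares of banana
per five-arcminute cell) and aligned layers of climate, terrain, soil,
irrigation and socio-economic variables, we want to (i) describe the
conditions production actually occupies, (ii) project where those
conditions will exist under a future climate, and (iii) estimate how
climate-dependent yield potential changes where banana is grown today.
`bananaclim` implements that chain of analysis, together with the
post-processing and validation arithmetic used when the plantation map
itself comes from a satellite classifier.

## The rectilinear envelope model

The niche model is deliberately simple: for each variable we take the
interval that contains the central 90% of the *banana-area-weighted*
distribution over grid cells — the weighted 5th and 95th percentiles,
called R90 — and declare a cell optimal when every variable lies inside its
interval. Weighting by crop area (rather than treating each occupied cell
equally) focuses the envelope on where production is concentrated, and the
box structure keeps every bound interpretable in the variable's own units.
The level (0.90) is a parameter of `estimate_r90()` and `build_criteria()`;
raising it can only widen envelopes.

Weighted quantiles use a left-continuous inverse-CDF convention: the
smallest value at which the cumulative weight fraction reaches `q`, with no
interpolation. With equal weights this is the type-1 sample quantile. The
convention was chosen because it is deterministic, exactly reproducible
across platforms, and trivially checkable against a brute-force oracle that
expands each cell into copies proportional to its weight (the test suite
does exactly that on hundreds of random instances). Membership in every
envelope is *closed* (`lower <= x <= upper`), which makes the ">= 90%
weighted containment" property of the estimated interval exact rather than
approximate at ties.

## Irrigation stratification and the precipitation adjustment

Irrigation decouples production from rainfall, so a single precipitation
envelope would misrepresent both rainfed and irrigated production. Cells
are split at a threshold on the area equipped for irrigation (AEI): at or
below the threshold is the low stratum, strictly above is the high stratum
(the boundary cell is deliberately placed in the low stratum, matching the
"0–5%" description of the source analysis). The default threshold is the
banana-area-weighted median AEI, which lands near 5%; `run_pipeline()` and
the generator fix it at exactly 0.05.

Climate envelopes (mean annual temperature BIO1, temperature seasonality
BIO4, annual precipitation BIO12) are estimated per stratum. The applied
precipitation envelope for the high stratum is then
`[own 5th percentile, rainfed 95th percentile]`: irrigated production can
happen under low rainfall, but the *absence* of irrigated plantations in
very wet areas reflects where irrigation gets built, not a tolerance limit,
so the rainfed upper bound is retained. The static constraints (elevation,
soil pH, population density, port distance) are estimated unstratified,
plus a minimum cropland-cover fraction (default 0.01) that restricts the
analysis to agriculturally plausible cells.

Two open choices were resolved as follows. *Static envelopes are two-sided
by default*: the same central-interval treatment as every other variable,
so sparsely populated cells and cells implausibly close to a port (where
cities, not plantations, sit) can be excluded; a `one_sided_static` switch
drops the lower bound for port distance and elevation and the upper bound
for population, for users who prefer pure threshold semantics. *Port
distance is great-circle* (haversine, R = 6371.0088 km) from the cell
centre to the nearest port, with no coastline routing; at the five-arcminute
scale of the analysis the difference is immaterial compared with the width
of the envelope.

Under the unrestricted-irrigation scenario each per-stratum climate
envelope is replaced by the union interval of the two strata and applied to
every cell: the widest conditions attainable if irrigation could be
established wherever needed. Because every merged interval contains both
per-stratum intervals, the unrestricted suitable area can never be smaller
than the stratified one — a property the tests verify on every scenario.

## Projection, categorization and attribution

Future suitability re-applies the same criteria with the three climate
layers swapped to the future period, holding AEI, cropland, soil pH,
population and ports at current values. Cells are then classified into
eight categories by observed presence (banana area > 0), current and future
suitability (`o±c±f±`); category areas partition the analysed area exactly,
using spherical cell areas `A = R² Δλ (sin φ_top − sin φ_bot)`. Area change
is `(future − current)/current`, reported on both a km² and a grid-cell
basis (they differ only through the latitude dependence of cell area).
Single-driver masks swap only the temperature pair (BIO1, BIO4) or only
precipitation (BIO12), attributing change to warming versus drying. The
occupancy fraction — the share of predicted-suitable cells that carry
banana — is computed on a cell-count basis. Heat exposure is summarised as
the area-weighted mean of BIO5 (maximum temperature of the warmest month)
over a mask, per period.

## The beta yield response

Climate-dependent relative yield is the product `Y_C = Y_T · Y_P` of two
asymmetric beta responses parameterized by cardinal (min, opt, max) values;
the regional defaults are 20.0/26.8/29.4 °C and 85.5/2646/5307 mm. The
response is defined as exactly 0 at and beyond the cardinal extremes (the
continuous limit of the power term; this also keeps degenerate cardinal
configurations from producing 0^0 artefacts) and is strictly unimodal in
between. The change statistic is the plain difference `Y_Cf − Y_Cc` of
relative yields — not a ratio — so values live in [−1, 1]; per-region
summaries are banana-area-weighted medians and interquartile ranges, with
regions under 10 banana cells flagged as too thin to characterise a
distribution. Absolute yield (t/ha) and management effects are out of
scope.

## Map post-processing and validation

The plantation map behind a real analysis comes from a pixel classifier
whose raw output contains speckle. `patch_filter()` removes connected
components of the positive class smaller than a pixel threshold (default
50 pixels; at 10 m pixels the smallest retained patch is 0.5 ha, i.e.
commercial scale). Connectivity defaults to 8 (diagonal neighbours count)
and is configurable to 4; the labelling is a two-pass union-find, checked
in the tests against an independent breadth-first flood fill. Validation
metrics are the standard one-vs-rest accuracy, precision, recall and F1; a
metric with a zero denominator is `NaN` with a warning, except F1 for a
classifier with no positive predictions *and* no positives recalled, which
is reported as 0 by the usual degenerate-case convention. The classifier
itself (feature extraction, training) is intentionally not implemented —
this module consumes already-classified rasters.

## The synthetic scenario generator

`generate_scenario()` produces landscapes with the statistical structure
the analysis assumes, not realistic geography:

- smooth climate fields (Gaussian-filtered noise) with a latitudinal
  gradient and an elevational lapse (−6.5 °C km⁻¹) on temperature;
- AEI increasing where annual precipitation falls short of ~1500 mm and
  temperature exceeds ~25 °C, plus noise — so irrigation is anti-correlated
  with rainfall but some dry cells remain unirrigated;
- banana area placed only in cells inside designed "true" ranges (with
  stratum-specific precipitation ranges defaulting to the published
  912–3690 mm rainfed / 543–2356 mm irrigated bounds), with log-normal
  hectares per occupied cell;
- a future period equal to the current one plus a uniform warming offset
  (and optional precipitation multiplier).

The warming offset is calibrated by coarse-to-fine grid search so that the
suitable area — classified with envelopes estimated from the generated
banana distribution, exactly as the pipeline estimates them — shrinks by
the configured loss fraction (default 0.60) to within 0.5 percentage
points; an unattainable target is an error, not a silent approximation.
Occupancy of in-envelope cells defaults to 0.9 so that a 200 × 200 scenario
yields well over 10,000 weighted cells, enough for envelope recovery to be
sharp; the real-world occupancy of suitable areas is far lower, which
matters for none of the estimators (they weight by area, not by
suitability).

What passing tests on these scenarios shows is that the estimators recover
designed structure under the model's own assumptions — smooth fields, exact
envelope membership, uniform warming. They do not show robustness to
spatial autocorrelation in the *weights*, classifier noise in the banana
map, or non-uniform climate change, all of which affect real applications.

## Sizes, determinism and numerical choices

All randomness in a scenario flows from one integer seed through R's
default RNG stream; every stochastic test names its seed, and the pipeline
writes a manifest (configuration, package version, input checksums) beside
every run. The packaged analyses use 200 × 200-cell scenarios (40,000
cells, roughly a 17° × 17° window at five arcminutes) for study-scale
checks and 40–100-cell-wide grids for unit tests; envelope and loss
recovery are already stable at these sizes. Rasters are stored as ESRI
ASCII grids with a −9999 nodata sentinel and 17 significant digits, so a
write/read round trip is bit-exact; grid alignment (shape, origin,
resolution) is asserted by every multi-layer operation rather than assumed.
Aggregation treats nodata as zero for sums (conserving totals exactly) and
excludes it from means.

## Known limitations

The rectilinear envelope ignores interactions between variables (a cell hot
*and* dry is treated no differently than the two conditions separately);
envelopes inherit any bias in the underlying crop map; the future scenario
holds socio-economic layers fixed by construction; and cell-count versus
km² bases can diverge for analyses spanning wide latitude ranges — both are
always reported.
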