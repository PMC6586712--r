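---
title: "Nonnative plant stressor assessment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonnative plant stressor assessment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nnpi)
```

## The problem

Nonnative plants are a pervasive stressor in wetlands: they pre-empt space
and resources, shift community composition and structure, and are often
associated with human-mediated disturbance. In a national probability survey
of wetlands, each sampled site contributes species-by-plot percent-cover
observations from five 100-m² vegetation plots inside an assessment area,
and each probability site carries an areal survey weight (hectares of the
target wetland population it represents). This package turns those
observations into (1) per-site nonnative metrics, (2) a categorical
stressor-level indicator, (3) design-based estimates of the wetland area in
each stressor category with confidence intervals, and (4) exploratory
models of which site attributes predict elevated stress.

## Site metrics

For each taxon at a site visit, *frequency* is the percent of the protocol's
`n_plots` vegetation plots in which it occurred, and *site-level absolute
cover* is the mean of its per-plot percent covers over all `n_plots` plots —
plots where the taxon is absent contribute zero. The protocol fixes
`n_plots = 5`; a site with fewer recorded plots keeps the full denominator,
treating unobserved plots as true absences (a validation issue is raised if
plot ids exceed the protocol). Absolute covers are summable above 100%
across taxa because canopies overlap.

Three complementary nonnative metrics summarize a site:

* **relative cover** `= 100 × Σ cover(nonnative) / Σ cover(all taxa)` —
  pre-emption of space and resources;
* **richness** `=` number of distinct nonnative taxa — the risk that some
  taxon proves invasive;
* **relative frequency** `= 100 × Σ freq(nonnative) / Σ freq(all taxa)` —
  the number of foci from which nonnatives can spread.

"Nonnative" includes introduced, adventive and cryptogenic taxa. Taxa whose
status is undetermined count in the denominators only, so they can dilute
but never inflate the nonnative share — the conservative direction for a
stressor indicator. A vegetation-free site has all three metrics zero.

The **wetland index** is the cover-weighted mean of numeric wetland
indicator statuses (OBL = 1, FACW = 2, FAC = 3, FACU = 4, UPL = 5) over the
taxa with a defined status: 1 means entirely obligate-wetland vegetation, 5
entirely upland. The **importance value** of a taxon at a site is
`(frequency + cover) / 2`. Growth-habit absolute covers are sums of
site-level cover over the member taxa of each habit (forb, graminoid, vine,
shrub, tree), with nonnative trees and shrubs reported as one combined
woody group.

## The stressor-level decision matrix

Each metric is bracketed against three ascending exceedance cutpoints —
defaults relative cover (1, 15, 40), richness (5, 10, 15), relative
frequency (10, 30, 60) — giving a level of low, moderate, high or very
high. Boundary values take the lower category ("≤ c1" is low), matching the
way the cutpoints are written. The site's overall indicator is the
**highest** level across the three metrics (a max filter): exceedance on
any one avenue of stress is enough to move the site up. The cutpoints are a
professional-judgment calibration, so they are configurable
(`nnpi_thresholds()`), but the defaults are the published ones. For
two-class analyses the four levels collapse to low–moderate (`LM`) versus
high–very-high (`HVH`).

Worked examples: a site with relative cover 7% (moderate), richness 14
(high) and relative frequency 32% (high) is **high** overall; a site with
relative cover 80% (very high), richness 1 (low) and frequency 59% (high)
is **very high** overall.

```{r}
classify_site(nn_richness = 14, nn_rel_freq = 32, nn_rel_cover = 7)[
  c("level_cover", "level_richness", "level_freq", "overall")]
```

## Design-based estimation

Probability sites enter estimation with their areal weights \(w_i\). The
wetland area in category \(c\) is the Horvitz–Thompson total
\(\hat T_c = \sum_i w_i\,\mathbb 1[\text{site } i \in c]\); category areas
therefore sum exactly to the domain's total weight, and each is also
reported as a percent of that total. Population means use the ratio
estimator \(\hat\mu = \sum w_i y_i / \sum w_i\) with Taylor-linearised
residual contributions. Two-sided 95% intervals are
\(\text{estimate} \pm 1.96\,\widehat{SE}\) (normal quantile; the survey
sizes involved make a t correction immaterial), truncated at zero for
areas. CI nonoverlap is exposed as a convenience comparison flag, with no
multiplicity adjustment — the user carries that caveat.

Two variance estimators are available:

* **srs** — the with-replacement estimator
  \(\hat V(\hat T) = n\,\mathrm{var}(z)\) with \(z_i = w_i y_i\); always
  applicable, ignores spatial structure.
* **local** (default) — a local-neighborhood estimator for spatially
  balanced designs. Each site's contribution is contrasted with the
  weighted mean of its neighborhood (the 4 nearest sites by Euclidean
  distance, self included; `nbh_size` is configurable). Neighborhood
  weights start at \(1/\texttt{nbh\_size}\) and are iteratively rescaled so
  every site has unit total weight both as a centre and as a member; each
  neighborhood's weighted squared deviation is inflated by
  \(1/(1-\sum_k w_{jk}^2)\), the weighted-variance analogue of
  \(n/(n-1)\), which makes the estimator unbiased when contributions are
  spatially unstructured. Under a spatial trend it is markedly smaller than
  the srs estimate because the design's spatial balance has already removed
  that variation. With fewer sites than the neighborhood size it falls
  back to srs with a warning.

**Repeatability.** With revisit sites (a second within-season visit),
signal:noise for a metric is the variance across first visits (signal) over
the mean of squared revisit differences divided by two (noise); half the
squared difference of two independent equally noisy measurements is an
unbiased estimate of the measurement variance. Ratios above 2 are the
conventional bar for a metric to make ecological distinctions. Zero noise
with positive signal reports an infinite ratio; a metric constant
everywhere is an error (0/0).

## Composite disturbance index

Eight raw sub-indices (agricultural, residential/urban, industrial,
hydrologic and habitat modification pressures, two hydrologic-alteration
summaries, and soil heavy metals, in the field protocol this emulates) are
each min-max standardized to 0–10 across the sampled sites,
`(x − min)/(max − min) × 10`, then summed and scaled by 10/8 for an overall
index from 0 to 100. Standardization absorbs the units of each sub-index,
so the composite is invariant to affine rescaling of any raw input. The
min and max are taken over the dataset being analysed by default; fixed
reference ranges can be supplied for cross-dataset comparability. A site
missing any sub-index gets a missing overall value — no imputation, since
the formula presumes eight scores. A constant sub-index standardizes to 0
everywhere with a warning.

## Balanced random forest

The exploratory stage asks which site attributes predict the combined
stressor class. Defaults: 1000 trees, `mtry = floor(sqrt(p))`. Because HVH
sites are the minority (~28% under the default synthetic conditions), every
tree is grown on a balanced bootstrap: the same number of cases from each
class, the minority-class count, drawn with replacement within class.
Survey weights are not used — the model describes the sampled sites, not
the population. Performance is out-of-bag percent correctly classified
(overall and per class) by majority vote, with ties called HVH (the
stress-conservative direction). Variable importance is the unscaled mean
decrease in OOB accuracy under within-tree permutation; a predictor the
forest never uses scores exactly zero. Partial dependence pins a predictor
to each of 25 grid values spanning its 1st–99th percentile and averages the
predicted HVH probability over sites. Categorical predictors (ecoregion,
wetland type) use the forest's native categorical splitting rather than
one-hot encoding, which preserves their joint split semantics.

The default predictor roster is the eleven site attributes the data model
carries: wetland index, native richness, the five native growth-habit
covers, bareground, the overall disturbance index, ecoregion and wetland
type. Landscape covariates (precipitation, elevation, surrounding land
use) require GIS extraction outside this package's scope;
`build_rf_predictors(extra = ...)` accepts them as extra columns when
available.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` produces a survey with the structure the estimators
need: a species pool with a controllable nonnative fraction across the five
growth habits and OBL–UPL indicator mixes; per-site communities assembled
by wetness affinity (wetland-type wetness targets 1.5–2.6 on the indicator
scale, so the realized wetland index varies over roughly 1.3–3.7);
log-normal per-plot covers truncated to (0, 100], which reproduces wide
total-cover ranges; gamma areal weights (unequal inclusion); uniform
coordinates on the unit square; ~10% within-season revisits; and eight
gamma-noise disturbance sub-indices tied to a latent site disturbance level
that also raises nonnative occupancy odds when `disturbance_effect > 0`.
The baseline nonnative selection weight (0.35) was set so that roughly 72%
of sites fall in the combined LM class under the default thresholds — the
imbalance typical of national wetland surveys — and the per-ecoregion
multipliers make xeric and interior-plains strata more invaded than
mountain strata, mirroring commonly reported gradients.

Measurement error is injected at the metric level: every site visit's
observed nonnative covers are rescaled so the realized nonnative relative
cover equals truth plus Gaussian noise with SD `revisit_noise_sd`
(default 2 percentage points, clamped to [0, 100]). Half the mean squared
revisit difference therefore recovers `revisit_noise_sd²`, which is what
the signal:noise machinery estimates. Two consequences worth knowing:
richness and relative frequency carry **no** injected revisit noise (their
S:N is reported as infinite on default synthetic data), and the clamping
slightly shrinks the realized noise at sites with very low or very high
nonnative share.

The generator is deliberately not ecologically realistic: coordinates are
spatially unstructured (so the local variance estimator's advantage only
appears in constructed spatial-trend scenarios), taxa have no spatial
ranges or co-occurrence structure, and marginal distributions are not
calibrated to any real survey release. Passing tests therefore demonstrate
the correctness and statistical behavior of the estimators under known
conditions — not that real field data meet those conditions.

## Numerical choices and problem sizes

Percent values are carried as doubles end to end; nothing is rounded until
report output. Threshold bracketing uses exact comparisons, so a metric at
a cutpoint is reproducibly the lower level. The tests exercise: the full
integer grid richness 0–20 × frequency 0–100 × cover 0–100 against an
independent bracket oracle; metric agreement with a direct raw-table
summation oracle at 100 random sites (tolerance 1e-9); weight conservation
to 1e-9; CI coverage over 1000 replicate populations of 800 units sampled
200 at a time with size-biased inclusion; signal:noise recovery at 500
sites and 200 revisit pairs; and forest behavior (separable, permuted-label
and single-informative-predictor designs) at 500 sites and 1000 trees.
Those sizes keep the full suite within a couple of minutes on one core
while leaving Monte-Carlo error well inside the asserted tolerances.

## Known limitations

* Classification of multi-visit sites is per visit; population estimation
  uses first visits only. How repeat visits should be reconciled for
  classification is a protocol decision the package does not make.
* The local variance estimator assumes planar coordinates in consistent
  units; no great-circle support.
* The disturbance composite requires all eight sub-indices; sites missing
  any are reported missing rather than imputed.
* Taxonomic standardization (synonymy, rollup of infraspecific taxa) is
  upstream of this package: taxon ids are taken at face value.
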