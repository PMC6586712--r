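# nnpi — nonnative plant stressor assessment for wetland surveys

`nnpi` implements a complete analysis pipeline for assessing the stress that
nonnative (introduced, adventive and cryptogenic) plants exert on wetlands
sampled by a national-scale probability survey. It is written for wetland
ecologists and survey statisticians who have site × plot × species
percent-cover tables, taxon traits (native status, growth habit, wetland
indicator status), areal survey weights and per-site disturbance
sub-indices — or who want to study the behavior of these estimators on
synthetic surveys with known structure.

## What it computes

**Site metrics.** For each site visit (five 100-m² vegetation plots), three
complementary nonnative metrics:

- relative cover = 100 · Σ cover(nonnative) / Σ cover(all taxa)
- richness = number of distinct nonnative taxa
- relative frequency = 100 · Σ freq(nonnative) / Σ freq(all taxa),
  where a taxon's frequency is the percent of plots in which it occurred

plus native richness, growth-habit absolute covers, importance values
((frequency + cover)/2), and the cover-weighted wetland index
(Σ wisᵢ·coverᵢ / Σ coverᵢ, with OBL = 1 … UPL = 5).

**Stressor classification.** Each metric is bracketed against ascending
exceedance cutpoints — relative cover (1, 15, 40), richness (5, 10, 15),
relative frequency (10, 30, 60) — into low / moderate / high / very high,
and the site's overall indicator is the *highest* level across the three
metrics (a max filter). Levels collapse to LM vs HVH for two-class
analyses.

**Design-based inference.** Horvitz–Thompson estimates of the wetland area
(ha) in each stressor category — nationally, by ecoregion, by wetland
type — and population-weighted metric means, with standard errors from
either a local-neighborhood variance estimator for spatially balanced
designs or the with-replacement estimator, and two-sided 95% CIs.
Signal:noise repeatability (among-site variance over revisit variance) for
any metric from within-season revisit pairs.

**Disturbance index.** Eight raw disturbance sub-indices min-max
standardized to 0–10 across sites, summed and scaled by 10/8 into a 0–100
composite.

**Balanced random forest.** An exploratory classifier of LM vs HVH status
(1000 trees, mtry = √p, each tree grown on a minority-class-sized balanced
bootstrap) with out-of-bag percent correct, permutation importance (mean
decrease in accuracy) and partial-dependence curves.

**Synthetic surveys.** `generate_dataset(sim_config(...))` builds
fully-structured synthetic surveys (unequal weights, strata, revisits,
disturbance-linked invasion) so every stage is testable without field data.

## Worked example

```r
library(nnpi)

ds  <- generate_dataset(sim_config(n_sites = 200, seed = 42))
m   <- site_metrics(ds)
cls <- classify_nnpi(m)
table(cls$overall[cls$visit_no == 1])
#>       low  moderate      high very_high
#>        53        90        55         2

category_extent(ds$sites, cls, by = "national", variance = "local")
#>    category n_sites area_ha    lo    hi pct_of_domain
#> 1       low      44   23206 15087 31325         29.46
#> 2  moderate      77   32132 22530 41735         40.80
#> 3      high      47   22139 14418 29861         28.11
#> 4 very_high       2    1281     0  3082          1.63
```

Of the 200 simulated sites, 170 are first-visit probability sites; their
weights estimate a wetland population of ~78,800 ha, of which an estimated
29.7% (23,400 ha) sits in the combined high + very-high stressor classes,
with each category's 95% CI shown (`lo`, `hi`; truncated at zero). The
classification itself is pure arithmetic on the decision matrix:

```r
classify_site(nn_richness = 14, nn_rel_freq = 32, nn_rel_cover = 7)
#>   level_cover level_richness level_freq overall combined
#> 1    moderate           high       high    high      HVH
```

— moderate cover alone would not flag this site, but 14 nonnative species
occurring at 32% relative frequency push it to high.

Repeatability from the survey's revisit pairs:

```r
v <- data.frame(site_id = m$site_id, visit_no = m$visit_no,
                value = m$nn_rel_cover)
signal_to_noise(v, "nn_rel_cover")$ratio   # 45.6 over 20 revisit pairs
```

ratios above 2 are the conventional bar for a metric to be usable.

## The analysis workflow

`analysis/` contains the numbered drivers for a full synthetic-survey
study; each writes its tables under `results/`:

```sh
Rscript analysis/01_simulate.R            # 600-site survey + provenance
Rscript analysis/02_site_metrics.R        # per-site metrics, species table
Rscript analysis/03_classification.R      # stressor levels, LM/HVH split
Rscript analysis/04_population_estimates.R# extent, pop. means, signal:noise
Rscript analysis/05_disturbance.R         # 0-100 composite index
Rscript analysis/06_random_forest.R       # balanced RF, importance, PD
```

`run_pipeline(run_config(...))` performs the same sequence in one call.
`vignettes/nnpi-methods.Rmd` documents the models, assumptions, defaults
and limitations.

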