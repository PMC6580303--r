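# otterphen

Seasonal phenology and demographic risk analysis of mistargeted
predator–prey interactions, built around white shark (*Carcharodon
carcharias*) bites to southern sea otters (*Enhydra lutris nereis*) in
central California. Sharks do not eat otters — the bites are exploratory
mistargeting — yet bitten otters strand in growing numbers, and the
demographic most affected (immature and male animals) is the one on which
range expansion depends. The package is for quantitative ecologists and
stranding-network analysts who want these analyses reproducible on their
own records.

Three questions, three components:

* **When do interactions happen?** Circular (day-of-year) Gaussian kernel
  densities and CDFs for event streams — tagged-shark detections, seal
  census counts, human shark-bite incidents, shark-bitten strandings —
  with circular lags between their peaks (`estimate_density()`,
  `relative_density()`, `to_cdf()`, `phenology_lag()`).
* **Who gets bitten?** Contingency-table χ² tests (Yates-corrected 2×2 by
  default), exact-enumeration Wilcoxon rank tests, and a within-bin
  bootstrap of the male proportion with percentile intervals
  (`build_contingency()`, `chi_squared()`, `wilcoxon()`,
  `bootstrap_bias()`).
* **Is the season expanding?** A per-period bootstrap with
  truncated-normal date perturbation — each resampled stranding date is
  jittered with scale `max(floor, MAD/√n)` fitted to the period's
  seasonal spread — yielding the core 80% seasonal window per 3-year
  period and an OLS trend of the median bite date across periods
  (`season_by_bin()`, `core_interval()`, `median_trend()`).

A synthetic-data generator (`synthetic_config()`, `gen_strandings()`,
`gen_detections()`, `gen_incidents()`) emulates all three surveillance
streams with known ground truth, and `run_pipeline()` orchestrates the
whole sequence from a single seeded configuration. A thin CLI
(`inst/cli/otterphen`, subcommands `simulate` / `run` / `report`) wraps
the same functions.

## Worked example

The package ships the published tri-annual summary of the 1997–2017
live-stranding record (431 strandings by period, sex, maturity and
cause). Expanding it to pseudo-records reproduces the demographic
battery:

```r
library(otterphen)

counts <- otter_stranding_counts()
recs   <- counts_to_records(counts$cells)

tab <- build_contingency(recs, "maturity", "cause", strata = list(sex = "M"))
chi_squared(tab)
#>   statistic   value    df p_value yates
#> 1 chi_squared  6.92     1 0.00853 TRUE
```

Among male strandings, mature animals are over-represented in the
shark-bitten column (χ² = 6.92, df = 1, p < 0.01). The adult male bias
under the pooled bootstrap:

```r
adult_shark <- counts_to_records(
  dplyr::filter(counts$cells, maturity == "mature", cause == "shark"))
bootstrap_bias(adult_shark, bootstrap_config(seed = 1), grouping = "pooled")
#>   n_records male_count median lower upper n_replicates grouping
#> 1        74         58  0.784 0.689 0.865         1000 pooled
```

A median male proportion of 0.78 (95% CI 0.69–0.87) among adult
shark-bitten strandings, against 0.42 for other causes (same call on the
`cause == "other"` stratum). The full pipeline on the default synthetic
study system:

```r
bundle <- run_pipeline(run_config(synthetic = TRUE, seed = 1))
bundle$season$summary
#>   bin n_records start_doy end_doy length_days length_months
#> 1   0         4     245.     282.        36.8          1.21
#> 2   1         5     232.     295.        63            2.07
#> ...
#> 7   6        47      96.8    287.       190.           6.25
bundle$trend
#>   slope slope_se r_squared total_advance_days
#> 1 -14.9     3.59     0.545               89.4
```

The estimated core windows lengthen from about 1 month to over 6 months
across the seven periods, and the median bite date advances about 15
days per period (bootstrap SE 3.6) — the generator's configured truth is
a 13.73-day advance with windows growing 60→240 days, recovered within
the resampling uncertainty at the study's own per-period sample sizes
(4–47 shark-bitten strandings).

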