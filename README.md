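# phenindex

Herbarium specimens are a long temporal record of plant reproductive
phenology, and instance-detection models can now count the reproductive
structures on digitised sheets automatically. Those automated counts,
however, systematically *undercount* organs. `phenindex` provides the
statistical machinery to work with such data anyway:

* **Phenological Index (PI) scoring.** For a sheet with counts of four
  organ classes — buds (index 1), flowers (2), immature fruits (3),
  mature fruits (4) — the PI is the proportion-weighted mean of the
  class indices,

  ```
  PI = sum_i P_i * i,   i = 1..4,
  ```

  where `P_i` is the proportion of reproductive structures in class
  `i`. It runs from 1 (a sheet bearing only buds, the start of the
  reproductive cycle) to 4 (only ripe fruits, its end), and because it
  depends on the *composition* rather than the abundance of organs it
  is robust to detectors that miss a constant fraction of each class.

* **Detector evaluation.** Signed per-class counting errors
  (`e = predicted − manual`; positive means the detector overcounts),
  per-class mean absolute error, Pearson/OLS concordance of predicted
  on manual values, detection ratios (manual organs per detected
  organ), error distributions binned by organ abundance, and
  regressions of transformed error magnitude on collection year
  (does specimen age degrade scoring?).

* **PI-controlled phenological models.** Two fixed OLS model sets for
  collection day-of-year (DOY): a temporal-shift model
  `doy ~ year + pi + elevation + latitude + longitude` and a
  phenoclimatic model `doy ~ pi + winter_ppt + spring_tmax`, each
  fittable with the manual- or the machine-derived PI, reported with
  95% t-based confidence intervals and per-term partial R². Models are
  compared by closed-interval CI overlap, and the coefficients convert
  into ecological quantities: days of flowering shift per century and
  days per PI unit of phenological progression (×3 for the full
  bud-to-ripe-fruit cycle).

* **A synthetic-collection generator** (`simulate_collection()`):
  seed-reproducible sheets with realistic organ totals, a latent
  reproductive stage driving both the organ composition and the DOY,
  elevation-dependent spring temperature, log-normal winter
  precipitation, and a detector emulated by class-specific binomial
  thinning — so the entire chain runs and can be calibrated with no
  external data.

The intended users are phenologists and ecoinformaticians evaluating
automated organ detection against manual scoring, or building
phenoclimatic models from scored herbarium collections.

## Worked example

```r
library(phenindex)

x <- simulate_collection(simulation_config(n_specimens = 709, seed = 1))

head(pi_table(x, "manual"), 3)
#>         id   pi
#> 1 SYN00001 3.00
#> 2 SYN00002 1.86
#> 3 SYN00003 1.27

evaluation_report(x)
#>            target   n   mae pearson_r slope slope_se intercept   r2
#> 1            buds 709 22.03      0.98  0.16   0.0014    -0.131 0.95
#> 2         flowers 709 21.07      0.94  0.22   0.0028     0.202 0.89
#> 3 immature_fruits 709  7.57      0.91  0.31   0.0053    -0.067 0.83
#> 4   mature_fruits 709  9.32      0.96  0.27   0.0029     0.051 0.93
#> 5              pi 707  0.13      0.98  0.97   0.0067     0.140 0.97
```

The detector finds only 0.16 predicted buds per manual bud — about 1
bud for every `round(detection_ratio(0.16), 1)` = 6.2 actually present
— yet the PI concordance slope is 0.97: organ *composition* survives
undercounting that organ *counts* do not.

```r
pc_m <- phenoclimatic_model(x, "manual")
pc_p <- phenoclimatic_model(x, "predicted")
pc_m
#>         term  estimate       se    ci_low    ci_high t_ratio  partial_r2
#>  (Intercept) 215.00000 2.344000 210.40000 219.600000  91.710          NA
#>           pi  16.74000 0.618400  15.53000  17.960000  27.070     0.50970
#>   winter_ppt   0.00716 0.001431   0.00435   0.009971   5.002     0.03427
#>  spring_tmax  -5.28400 0.093540  -5.46800  -5.101000 -56.500     0.81910
#> n = 709, residual df = 705, full-model R2 = 0.848

compare_models(pc_m, pc_p)$overlap
#> [1] TRUE TRUE TRUE
```

Flowering advances ~5.3 days per °C of spring maximum temperature and
delays ~0.7 days per 100 mm of winter precipitation — and the manual-
and machine-PI fits are statistically indistinguishable (all 95% CIs
overlap). Derived quantities:

```r
tm_m <- temporal_shift_model(x, "manual")
tm_p <- temporal_shift_model(x, "predicted")
shift_per_century(tm_m, tm_p)
#> [1]  4.4 12.4        # days of flowering advance per century
progression_days(tm_m, tm_p, pc_m, pc_p)$full_cycle_days
#> [1] 45.6 54.5        # days from first buds to ripe fruits
```

An end-to-end run (`run_pipeline()`, or the CLI in
`inst/cli/phenindex.R`) writes all of the above as CSV reports plus a
plain-text summary and the resolved YAML configuration.

## Package layout

* `R/organ-counts.R`, `R/specimens.R` — PI, schema, CSV I/O
* `R/detection-eval.R` — errors, MAE, concordance, bins, age effects
* `R/pheno-models.R` — model sets, partial R², comparison, derived
  quantities
* `R/simulate.R` — synthetic collections
* `R/coco.R` — per-image counts from COCO-style annotation JSON
* `R/pipeline.R`, `inst/cli/phenindex.R` — end-to-end pipeline and CLI
* `vignettes/phenological-index-pipeline.Rmd` — methods and design
  notes
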