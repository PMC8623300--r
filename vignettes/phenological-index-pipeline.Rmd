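---
title: "Scoring and modelling herbarium phenology from organ counts: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and modelling herbarium phenology from organ counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenindex)
```

This vignette explains the statistical model behind `phenindex`, the
assumptions it makes, the parameters that matter, and the design
decisions taken where more than one defensible choice existed.

## 1. The Phenological Index

A scored herbarium sheet carries counts of four classes of reproductive
structures, ordered by developmental progression: flower buds (index
value 1), open flowers (2), immature fruits (3) and mature fruits (4).
The Phenological Index is the proportion-weighted mean of the index
values,

$$\mathrm{PI} = \sum_{i=1}^{4} P_i \, i ,$$

with $P_i$ the proportion of structures in class $i$. It is
dimensionless, lies in $[1, 4]$, equals 1 exactly when only buds are
present and 4 exactly when only mature fruits are, and is invariant
under uniform scaling of all counts. That last property is the whole
point: a detector that misses a constant fraction of every organ class
changes the counts drastically but leaves the expected PI untouched, so
the PI is the natural quantity to carry from automated scoring into
downstream models.

```{r}
phenological_index(c(25, 0, 0, 0))   # only buds
phenological_index(c(5, 5, 5, 5))    # an even mixture
```

**Zero-total sheets.** A sheet with no reproductive structures has an
undefined PI. We treat this as an error rather than returning 0 or a
silent `NaN`: a scored collection consists of fertile sheets, and an
infertile row almost always indicates an upstream filtering problem.
The pipeline default (`zero_total = "skip"`) drops such rows with a
logged warning that names them.

**Day-of-year bounds.** `doy` is validated against $[1, 366]$ rather
than the 1–365 convention, because real collections contain
December-31 records from leap years.

## 2. Evaluating a detector against manual counts

The per-class counting error on sheet $i$ is the signed difference

$$e_{i,k} = \hat c_{i,k} - c_{i,k},$$

where $\hat c$ is the detector's count and $c$ the manual count, so a
positive error means the detector *over*estimates. The per-class mean
absolute error is $\mathrm{MAE}_k = \frac{1}{N}\sum_i |e_{i,k}|$.
Concordance is summarised two ways, both via `concordance()`: the
Pearson correlation between predicted and manual values, and an OLS
regression of predicted on manual values whose slope is the expected
number of predicted organs per manual organ. The reciprocal slope
(`detection_ratio()`) reads as "one detected organ per $1/b$ organs
actually present".

Abundance-binned error distributions (`bin_errors_by_abundance()`) use
fixed-width bins of 10 organs with an open top bin (0–9, 10–19, …,
40+), configurable; empty bins are retained with $n = 0$ and flagged,
never silently dropped.

**Specimen-age effects.** `age_effect()` regresses a transformed error
magnitude on collection year. For organ classes the response is
$\log_{10}(|e| + 1)$ — the offset rescues the many zero-error sheets
before the log. For the PI the response is
$\sqrt{|\mathrm{PI}_{pred} - \mathrm{PI}_{manual}|}$ with no offset:
$|\Delta \mathrm{PI}|$ is bounded in $[0, 3]$ and has no zero-inflation
problem that an offset would need to fix. Slopes are therefore in
transformed units per year; report-level arithmetic that multiplies a
coefficient by an interval of years (e.g., per-century differences) is
deliberately linear and makes no attempt to back-transform.

## 3. The two model sets

Two fixed OLS formulas model the day of year of collection (DOY), a
standard proxy for flowering date, while controlling for the
phenological status of each specimen:

* temporal shift: `doy ~ year + pi + elevation + latitude + longitude`
* phenoclimatic: `doy ~ pi + winter_ppt + spring_tmax`

There is deliberately *no* model selection: the package's purpose is to
compare the same reasonable formula fitted with a manual-count PI
versus a machine-count PI, not to find the best climate predictors.
Conventions:

* Predictors enter untransformed and uncentred, so coefficients are in
  raw units (days/year, days per PI unit, days/m, days/°C, days/mm).
* 95% confidence intervals use $t$ quantiles with residual degrees of
  freedom.
* Partial $R^2$ for a single-df term is computed as
  $t^2/(t^2 + \mathrm{df}_{res})$, the squared partial correlation;
  this is algebraically the SSE comparison
  $(\mathrm{SSE}_{reduced} - \mathrm{SSE}_{full})/\mathrm{SSE}_{reduced}$
  of the full model against the model with the focal term dropped, and
  the test suite verifies that identity against explicit refits.
* Rank-deficient designs (constant or exactly collinear regressors)
  are an error naming the offending terms, not a silent `NA` column.

**Model comparison.** `compare_models()` tests, per shared substantive
term, whether the two 95% CIs overlap as *closed* intervals — touching
endpoints count as overlap. This is conservative (it favours declaring
two fits indistinguishable) and matches how CI-overlap comparisons are
ordinarily read in the phenology literature. All specified terms are
always retained in derived-quantity computations, significant or not.

**Derived quantities.** The year coefficient's CI bounds scale by 100
into days of flowering shift per century (`shift_per_century()`,
magnitudes). The PI coefficient's bounds are days per PI unit of
phenological progression; across several supplied models the interval
is the envelope (minimum lower bound to maximum upper bound), and the
full bud-to-ripe-fruit cycle is 3× that, since the PI spans three units
(`progression_days()`). Both conversions are linear, and both keep full
precision — rounding happens only in report output.

## 4. The synthetic-collection generator

`simulate_collection()` exists so the entire analysis chain can be
exercised, calibrated and regression-tested without any external
deposit. Per specimen it draws, in this fixed order: site (uniform
latitude, longitude, elevation over a montane western-North-American
window), collection year (uniform over 1900–2013), climate, a latent
reproductive stage, organ counts, DOY, and detector counts.

The component models, with defaults and why:

* **Climate.** Spring maximum temperature declines with elevation,
  $T_{max} = 26 - 0.0065\,\mathrm{elev} + \mathcal N(0, 1.5^2)$ °C —
  a standard environmental lapse rate of 6.5 °C/km, giving a ~2–26 °C
  range over the 150–3200 m elevation window. Winter precipitation is
  log-normal (meanlog $\log 600$, sdlog 0.55 mm), right-skewed with a
  ~90–2200 mm bulk, as mountain precipitation records are.
* **Latent stage.** $u \sim \mathrm{Uniform}(0, 3)$,
  $\mathrm{PI}_{true} = 1 + u$: collections sample plants across the
  whole reproductive cycle.
* **Organ counts.** Expected count of class $k$ is
  $\lambda_k(u) = (\mu_k/\kappa_k)\exp\{-(k - \mathrm{PI}_{true})^2 /
  (2\tau^2)\}$ — a Gaussian kernel over the class indices centred on
  the latent stage, with $\tau = 0.6$ controlling class mixing, scaled
  by the target class means $\mu_k$ = 27.4 buds, 28.5 flowers, 11.0
  immature fruits, 12.5 mature fruits per sheet. The normaliser
  $\kappa_k$ is the kernel's stage-averaged mass (available in closed
  form), so the *marginal* per-class means equal $\mu_k$ exactly —
  without it, a bare kernel would equalise the classes and miss the
  configured means. The sheet total is negative binomial (size 3,
  mean $\sum_k \lambda_k(u)$, i.e. ≈ 79 organs marginally) for
  realistic overdispersion; zero totals are redrawn because a scored
  collection contains fertile sheets only; the composition is a
  multinomial split of the total with probabilities
  $\propto \lambda_k(u)$.
* **DOY.** $\mathrm{DOY} = 232 - 0.10(\mathrm{year} - 1950)
  - 5.3\,T_{max} + 0.0072\,\mathrm{PPT}
  + 17\,(\mathrm{PI}_{manual} - 1) + \mathcal N(0, 15^2)$, rounded and
  clamped to $[1, 366]$ (clamping is inactive in practice at the
  defaults; mean DOY ≈ 182, SD ≈ 38). DOY is driven by the
  phenological status the sheet *displays* — the PI of its manual
  counts — rather than by the latent stage. This was a genuinely open
  design choice: driving DOY by the latent stage is arguably the
  cleaner causal story, but the displayed PI is itself only a noisy,
  edge-compressed function of the stage (a multinomial composition
  over four discrete classes cannot resolve the stage near the scale
  ends), so under that alternative the PI coefficient that downstream
  regressions estimate is attenuated by a few percent relative to the
  configured progression rate and the generator would not mean what
  its parameter says. Driving DOY by the displayed PI makes the
  configured 17 days/PI unit the true coefficient of the covariate the
  models actually see, which is the property a calibration tool must
  have.
* **Detector.** Predicted counts are class-specific binomial thinnings
  of the manual counts with detection probabilities 0.16 (buds), 0.22
  (flowers), 0.30 (immature fruits), 0.28 (mature fruits). The bud,
  immature-fruit and mature-fruit rates are the kind of class-specific
  recall an instance detector shows on crowded sheets; the flower rate
  is an interpolation between its neighbours and is documented as
  arbitrary. An optional `age_error_rate` lets detection probability
  drift linearly with specimen age to emulate pigment fading.

**What the generator does and does not emulate.** It reproduces the
count magnitudes and overdispersion, the stage-driven composition, the
climate/DOY coefficient structure, and class-specific undercounting.
It does *not* emulate detector false positives, occlusion geometry
(which makes real counting error grow superlinearly with abundance),
spatially structured climate, or any true joint distribution of stage
and date — that joint distribution is unknowable from summary
statistics, so the generator is an assumptions-explicit stand-in, not
a calibrated emulator. Tests passing on synthetic collections
demonstrate that the *machinery* is correct under the stated
assumptions, not that any particular field collection satisfies them.

A consequence worth knowing: under class-specific thinning the
synthetic PI concordance exceeds every per-class count concordance at
the defaults — compositions survive thinning better than counts — but
binomial thinning alone keeps per-class count correlations far higher
than real detectors show, because it lacks the abundance-dependent
error inflation of crowded sheets.

## 5. Numerical and testing choices

* PI values, slopes and ratios are kept at full floating precision
  everywhere; rounding (half-even, via R's `round()`) happens only at
  report boundaries.
* The PI implementation is verified against exhaustive enumeration of
  every count composition with totals up to 12 (~1,800 cases, 1e-12
  tolerance), plus scale-invariance and single-organ monotonicity
  properties.
* All regression output is verified against explicit normal-equation
  and SSE-refit oracles at 1e-10.
* Monte-Carlo checks use fixed seeds and moderate sizes chosen for
  sharpness at interactive runtimes: 2,000 sheets for generator
  moments (≈3 standard errors of discrimination), 10,000 sheets for
  thinning robustness, 700 sheets × 20 seeds for CI-coverage
  calibration of the model coefficients (the CIs are exact under the
  generator, so 18/20-or-better coverage per parameter is the
  expected behaviour, with progression-rate coverage assessed against
  the cross-model CI envelope that `progression_days()` defines).
* Uniform thinning leaves the PI of *expected* counts exactly equal to
  the manual PI; on realised counts the mean $|\Delta\mathrm{PI}|$ on
  sheets with ≥ 40 organs stays below 0.05 for detection rates in
  $[0.4, 0.8]$ and degrades gracefully, but remains measurably larger,
  at rates down to 0.2, where only ~8 detected organs remain to
  estimate a composition — composition noise at that sampling depth
  bounds what any proportion-based index can do.

## 6. Known limitations

* The detector model is pure thinning: no false positives, no
  class-confusion (a bud detected as a flower), no spatial occlusion.
  Real detector evaluations should expect lower per-class concordance
  than the generator produces.
* The phenological models are ordinary least squares with independent
  errors; there is no spatial or temporal autocorrelation structure,
  no mixed effects, and no alternative climate windows.
* `counts_from_coco()` reduces annotations to instance counts per
  category; it does not read segmentation geometry.
* The CI-overlap comparison is a conservative screen, not a formal
  equivalence test; non-overlap of 95% CIs is a stricter criterion
  than a 5%-level test of coefficient equality.
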