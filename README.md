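# aortaZ

Z-score reference charts for fetal ascending-aorta diameters and diameter
distensibility.

## The problem

Fetal echocardiography can measure the inner diameter of the ascending
aorta at the sinotubular junction at end-systole (Dmax) and end-diastole
(Dmin). Their relative difference,

```
DD = (Dmax − Dmin) / Dmin,
```

is the *diameter distensibility* — a blood-pressure-free surrogate for
arterial elasticity, usable in fetuses where blood pressure cannot be
measured non-invasively. All three quantities change systematically across
gestation (the diameters grow, distensibility falls), so a raw value is
meaningful only relative to a gestational-age-conditional reference. The
standard formalisation is the heteroscedastic Gaussian chart

```
y | x ~ N( μ(x), σ(x)² ),          Z = (y_obs − μ(x)) / σ(x),
```

with μ a low-order polynomial in the predictor x (gestational age, BPD or
femur length) and σ a linear function of x, each fitted by its own
regression. `|Z| > 1.65` flags the outer 10% of the reference population;
percentile curves are `μ(x) + Φ⁻¹(p/100)·σ(x)`.

`aortaZ` is for perinatal researchers and sonographers who want to

* score measurements against the published equations for Dmax, Dmin and DD
  versus GA, BPD and FL (with the typographically corrupt printed entries
  shipped both verbatim and in a sanitized, usable form),
* build such charts from their own cohorts with the classical three-step
  procedure (mean fit → SD fit → Z-scores),
* check chart calibration (P-P plots, Shapiro–Wilk, 90%-band coverage,
  trend balance), and
* quantify measurement repeatability with ANOVA-based intraclass
  correlation coefficients (ICC(1,1), ICC(2,1) agreement, ICC(3,1)
  consistency, with exact F-based confidence intervals).

A seeded synthetic-cohort generator reproduces the statistical structure
the pipeline assumes, so everything is testable end-to-end without patient
data.

## Worked example

Score an observed distensibility of 0.105 (10.5%) at 24 weeks against the
published sanitized charts:

```r
library(aortaZ)
reg <- published_registry()          # sanitized variant (default)
score_record(list(ga = 24, dd = 0.105), "DD", "GA", reg)
#>   observed predicted_mean predicted_sd         z  band_flag response predictor  x extrapolated
#> 1    0.105      0.3219315       0.0788 -2.752938 outside_90       DD        GA 24        FALSE
```

The fetus sits 2.75 SD below the predicted mean distensibility for 24
weeks — outside the central 90% band, i.e. abnormally stiff for its age.
(Scoring the same observation against the worked-example chart of the
source publication, mean 0.344 and SD 0.0816, gives Z = −2.93.)

Build a chart from a cohort and check its calibration:

```r
cohort <- simulate_cohort(n = 490, seed = 1)     # or read_cohort("cohort.csv")
fit <- build_reference_chart(cohort, "DD", "GA")
fit
#> <reference_chart> DD ~ GA on [18.0404, 39.9137]
#>   mean: Y = 0.689086 + -0.0010058*GA^2 + 1.55203e-05*GA^3
#>   sd:   Y = 0.133958 + -0.00238506*GA
#>   training: n = 490, mean z = -0.000, sd z = 1.007, outside 90% band = 9.2%

round(unlist(diagnostics_report(fit$zscores$z, fit$zscores$x)), 4)
#> pp_max_deviation        shapiro_p    coverage_1645     coverage_196
#>           0.0256           0.4617           0.1020           0.0510
#>    balance_slope        balance_p
#>           0.0000           0.9990
```

Training Z-scores are standard normal (Shapiro–Wilk p = 0.46), 10.2% fall
outside the 1.6449 band (expected: 10%), and there is no residual trend
across gestation (slope ≈ 0) — a calibrated chart.

Percentile curves and repeatability:

```r
as.data.frame(percentile_curves(reg[["Dmax~GA"]], c(20, 28, 36)))
#>   percentile  x    value
#> 1          5 20 2.072058
#> ...                           # 5th/50th/95th reference lines, mm

tb <- simulate_repeatability(n_subjects = 20, k = 2, parameter = "dd", seed = 11)
icc(tb, "ICC_1_1")
#> <icc> ICC_1_1 = 0.9777  95% CI [0.9455, 0.9910]  (n = 20 subjects, k = 2)
```

A thin command-line wrapper over the same functions lives at
`inst/cli/aortaz.R` (subcommands `simulate`, `fit`, `score`, `curves`,
`diagnose`, `icc`).

See `vignettes/aorta-reference-charts.Rmd` for the full account of the
model, the sanitization of the corrupt printed equations, the synthetic
generator's assumptions, and numerical policy.

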