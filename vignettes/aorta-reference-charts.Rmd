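---
title: "Reference charts and Z-scores for fetal ascending-aorta diameter and distensibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference charts and Z-scores for fetal ascending-aorta diameter and distensibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aortaZ)
```

## The problem

The elastic behaviour of the fetal ascending aorta is of interest because
congenital heart disease and growth restriction leave measurable traces in
arterial elasticity before birth. Most elasticity indices (compliance,
stiffness index, Peterson's modulus, pulse-wave velocity) require blood
pressure, which cannot be measured non-invasively in a fetus. *Diameter
distensibility* sidesteps this: it is the relative systolic–diastolic
expansion of the vessel,

$$\mathrm{DD} = \frac{D_\max - D_\min}{D_\min},$$

where $D_\max$ is the inner diameter of the sinotubular junction in the
frame before aortic-valve closure (end-systole) and $D_\min$ in the frame
before valve opening (end-diastole). `aortaZ` stores DD as a dimensionless
fraction; percent is a display transformation (`dd_percent()`). The
magnitudes of the shipped reference equations (a mean of 0.344 and an SD
near 0.08 at 24 weeks) are on the fraction scale, and keeping one internal
scale removes a whole class of unit bugs.

Because every diameter grows with gestation, a raw measurement is
uninterpretable without conditioning on fetal age or size. The standard
device is a conditional reference chart and its Z-score.

## The three-step chart model

For a response $y$ (Dmax in mm, Dmin in mm, or DD) and a predictor $x$
(gestational age GA in weeks, biparietal diameter BPD in mm, or femur
length FL in mm) the model is Gaussian with age-varying moments:

$$y \mid x \;\sim\; N\!\big(\mu(x),\, \sigma^2(x)\big),$$

with $\mu$ a low-order polynomial and $\sigma$ a linear function of $x$.
Construction proceeds in three steps.

**Step 1 — mean.** `select_best_model()` fits every candidate term set by
ordinary least squares (`stats::lm`) and keeps the winner by adjusted
$R^2$ (AIC is available). Candidates are all non-empty subsets of powers
$\{1,2,3\}$ plus an intercept — the same heterogeneous family as published
fetal-biometry equations (pure linear up to mixed cubic forms). Exact ties
go to fewer terms, then to lower maximum power. The reported fit statistics
are the multiple correlation $R$ and the overall-F $p$-value, the two
columns reference tables conventionally print.

**Step 2 — SD.** Heteroscedasticity is modelled by its own regression:
residuals from step 1 are grouped into predictor bins (1 week for GA, 5 mm
for BPD/FL — fetal BPD spans roughly 42–95 mm and FL 28–76 mm over 18–40
weeks, so 5-mm bins leave ≥ 10 usable bins), the per-bin SD is computed,
and a line is fitted through the (bin centre, bin SD) points. The fit is a
two-pass generalised least squares: a count-weighted first pass supplies
fitted SDs, after which the known Gaussian sampling variance of a bin SD,
$\sigma^2(x)/(2 n_b)$, provides the definitive weights and an exact
coefficient covariance $(X^\top W X)^{-1}$. The weighting matters because
late-gestation bins are sparse in clinical cohorts. An
`absolute_residual` alternative regresses $|r|$ on $x$ and rescales by
$\sqrt{\pi/2}$ (the half-normal mean-to-SD factor); the two methods agree
within 15% on well-behaved cohorts and the binned method is the default
because it treats the SD as the directly observed dependent variable.
Bins with fewer than `min_bin_count = 5` residuals are dropped.

**Step 3 — Z-score.**

$$Z = \frac{y_\text{obs} - \mu(x)}{\sigma(x)}.$$

$|Z| > 1.65$ (strict inequality; 1.65 itself is *within*) flags the outer
10% of the reference population. Inside percentile arithmetic the package
uses the exact quantile `qnorm(p/100)` — 1.6449 for the 95th — and reserves
the rounded 1.65 for band classification only, matching how such charts
are printed and used clinically. Percentile curves are
$\mu(x) + \Phi^{-1}(p/100)\,\sigma(x)$.

Out-of-range predictors **warn** (condition class `aortaz_extrapolation`)
but still return a number: a bedside calculator must not refuse to answer,
and the flag travels with the result.

## The published registry and its corrupt entries

`published_registry()` ships all nine mean and nine SD equations. Three
printed forms are typographically unusable:

* the **Dmin~GA mean** carries two linear terms and evaluates negative
  (about −63 mm at 24 weeks);
* the **DD~GA SD** (`0.140 − 0.255e−3·GA`) gives 0.134 at 24 weeks, while
  the source's own worked example divides by an effective SD of ~0.08
  there;
* the **DD~BPD SD** (`0.131 − 8.040e−3·BPD`) is negative for every fetal
  BPD.

The `"as_printed"` variant preserves all of this verbatim (with
SD-positivity validation off) for provenance and inspection. The default
`"sanitized"` variant applies the minimal, internally-consistent repairs:
single decimal-shift corrections to the two DD SD slopes (−2.55e−3 per
week and −8.040e−4 per mm, which restore positivity, reproduce the worked
example's effective SD at 24 weeks, and agree in magnitude with the intact
DD~FL SD model), and a Dmin~GA mean rebuilt from the identity
$D_\min = D_\max/(1+\mathrm{DD})$ applied to the two intact GA equations.
That ratio is rational in GA, so it is represented by a cubic least-squares
fit over a dense grid — accurate to ~0.006 mm, two orders of magnitude
below the Dmin SD. Sanitized models carry provenance
`"published_sanitized"` and keep the printed text in their `printed`
field; the choice of variant is always explicit and inspectable.

The worked example the package treats as its anchor — DD 0.105 observed at
24 weeks against mean 0.344 and SD 0.0816 gives $Z = -2.93$ — also pins the
fraction-scale reading of the tables: the printed divisor "0.816" cannot
reproduce the printed quotient −2.93, while 0.0816 does, so the package
takes the quotient as authoritative and treats the divisor as a
decimal-shift misprint.

```{r worked-example}
zscore(0.105, 0.344, 0.0816)
```

## What the synthetic cohort emulates — and what it does not

`simulate_cohort()` exists so that every pipeline stage is testable
without patient data. Its defaults are the study conditions: $n = 490$
fetuses, GA on 18–40 weeks (uniform by default; an `empirical_skewed`
option thins the <20- and >38-week tails to a quarter of the central
density, mimicking the sparsity real referral cohorts show at the
extremes), truth models from the sanitized registry. BPD and FL are linear
in GA (slopes 2.4 and 2.15 mm/week, anchored at ~47/95 mm and ~33/76 mm at
20/40 weeks) plus Gaussian noise with SD 2 mm — standard biometry
magnitudes, since the reference equations themselves say nothing about the
joint biometry distribution.

DD and Dmax are drawn from the truth charts' Gaussians at each fetus's GA;
Dmin is then **derived** as $D_\max/(1+\mathrm{DD})$ rather than drawn, so
the three responses are exactly consistent and the printed (corrupt) Dmin
equation is never needed. The cost is that Dmin's marginal SD is induced
rather than set.

Draws are floored at physical minima (DD at 0.01, Dmax at 0.5 mm) by
rejection sampling, which avoids a point mass at the floor. The fractions
redrawn are recorded in the `truncation_fraction` attribute. For Dmax the
fraction is essentially zero; for DD it is not negligible near term —
the truth mean falls to ~0.067 at 40 weeks with SD ~0.038, putting a few
percent of late-gestation mass below the floor (about 0.8% of a uniform-GA
cohort overall). This is a property of the published truth models, not of
the generator; it mildly right-skews late-gestation DD, which is worth
remembering when reading normality diagnostics on DD charts.

What the generator does **not** emulate: measurement digitisation,
operator-dependent caliper bias, the correlation structure of repeated
clinic visits, non-Gaussian tails from image-quality failures, and any
relationship between aortic size and fetal weight centiles. Passing tests
on synthetic cohorts therefore demonstrate internal consistency of the
pipeline — charts fitted on data generated from known truth recover that
truth, Z-scores self-standardise, coverage lands at 10% — not the clinical
validity of the published equations.

`simulate_repeatability()` draws subject true values from the cohort model
and adds per-measurement noise: 0.05 mm for the diameters by default, and
0.02 for DD — a 0.05 *fraction* of noise on DD would drive its intraclass
correlation to ~0.89, below the ≥ 0.93 agreement this kind of study
reports, so the DD default is scaled to the parameter's units. An
interobserver design can add a constant rater offset, which depresses
absolute-agreement ICC but not consistency ICC.

## Repeatability: which ICC

The package computes single-measure ICCs from ANOVA mean squares:
one-way `ICC_1_1` (replicates exchangeable — the natural intraobserver
form), two-way absolute-agreement `ICC_2_1_agreement` (rater offsets count
against agreement — the natural interobserver form and the package
default), and the consistency form `ICC_3_1_consistency` for completeness.
Confidence intervals are the exact F-based Shrout–Fleiss bounds, with the
Satterthwaite degrees of freedom for the agreement form. The source study
reports only "ICC", and its printed values (0.930–0.991) cannot
disambiguate the model choice; the per-design defaults above are this
package's decision.

## Numerical and degenerate-input policy

* Polynomials are evaluated as exact term sums; chart JSON serialises
  coefficients at 17 significant digits so round trips are bit-exact.
* SD models are validated strictly positive on a 201-point grid at chart
  construction; a non-positive predicted SD at use time is a typed
  `chart_domain` error, never an `NaN` Z-score.
* P-P plots use the Hazen plotting position $(i-0.5)/n$ (`weibull`
  $i/(n+1)$ is available; they differ by $O(1/n)$). Shapiro–Wilk is the
  formal companion to the visual check and inherits R's 3–5000 sample
  limits.
* All-zero residuals, constant predictors, rank-deficient designs, empty
  grids and single-column rating tables all raise typed errors
  (`aortaz_non_positive_sd`, `aortaz_degenerate_input`,
  `aortaz_singular_fit`, `aortaz_empty_input`, `aortaz_degenerate_table`),
  so callers can dispatch rather than parse messages.
* Model selection is deterministic: identical cohorts and configuration
  give bit-identical charts.

One behavioural note on selection: with the adjusted-$R^2$ criterion a
pure-noise higher-order term joins the winning model whenever its $|t|$
exceeds 1, which happens in roughly a third of samples regardless of noise
level. This is inherent to the criterion (AIC shifts the threshold to
$\sqrt{2}$), and is why the candidate family is kept small and the
tie-break prefers parsimony; the *predicted curves* of the over-fitted and
true models are nearly indistinguishable even when the selected support
differs.

## Problem sizes

The validation suite runs cohorts of 490 (the study scale) for calibration
and coverage checks, 2 000–5 000 for parameter-recovery and SD-method
agreement checks, and 200 replicate fits for the Monte-Carlo rates
(coefficient coverage within 3 SE, Shapiro–Wilk pass rates). The
end-to-end band-coverage figure is averaged over 50 seeded 490-fetus
cohorts.

## A complete worked run

```{r pipeline}
cohort <- simulate_cohort(n = 490, seed = 1)
fit <- build_reference_chart(cohort, "DD", "GA")
fit

unlist(diagnostics_report(fit$zscores$z, fit$zscores$x))

curves <- percentile_curves(fit$chart, seq(18, 40, by = 0.5))
head(as.data.frame(curves))
```

## Known limitations

* The reference equations are single-predictor by design; no multivariable
  or skewness/kurtosis (LMS/GAMLSS-style) modelling is attempted because
  the underlying charts assume Gaussian residuals throughout.
* The sanitized registry is a reconstruction: faithful to the intact
  printed equations and the worked example, but a reconstruction
  nonetheless; the as-printed variant is always available for audit.
* Synthetic validation bounds what can be claimed about real cohorts (see
  above).
* BPD/FL-based scoring inherits the linear biometry approximation of the
  generator only in tests; scoring real measurements uses the measured
  BPD/FL directly and is unaffected.
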