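---
title: "Methods: empirical models of pregnancy and gestation physiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: empirical models of pregnancy and gestation physiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pregphys)
```

## Scope and intent

`pregphys` is a repository of closed-form empirical models for the
anatomical and physiological quantities that a physiologically based
pharmacokinetic (PBPK) model of a human mother and fetus needs as
time-varying parameters: compartment volumes, blood flow rates, hematocrits
and glomerular filtration, all as functions of gestational age `t` in weeks
(time since the first day of the last menstrual period; fetal age, time
since fertilization, is `t - 2`). The package also implements the
calibration machinery by which such models are constructed from
summary-statistic data, so users can refit any model family to their own
data and repeat the selection procedure.

The curves describe an *average* healthy woman with a singleton, low-risk
pregnancy, and her fetus. They carry no population variability: each
quantity is a single deterministic function of age.

## Model families

Fourteen candidate families are supported (`model_families()`): polynomials
up to degree three, "growth" polynomials with no intercept (for quantities
that are zero at conception), Gompertz and logistic sigmoids with and
without an additive baseline, and allometric power laws (plain, with
baseline, and the quadratic-in-log-mass variant often used for scaling
fetal tissue masses to total body mass). The Gompertz parameterization is
fixed as

$$y(t) = \theta_0 \exp\!\left[\tfrac{\theta_1}{\theta_2}
  \left(1 - e^{-\theta_2 t}\right)\right],$$

with asymptote $\theta_0 e^{\theta_1/\theta_2}$; at $t = 0$ the curve
equals $\theta_0$. Logistic curves are evaluated through `plogis()`, which
works on the log scale internally, so user-supplied parameters that push
the exponent beyond $\pm 700$ return exact limits instead of overflowing.
Power laws at covariate zero use the continuity extension
$0^{\theta_1} = 0$ for positive exponents (the fetal-mass covariate is zero
at conception); negative exponents there are a domain error.

## Preferred models and alternates

Each registered quantity (see `quantity_registry()`, 48 rows) is bound to a
preferred model; statistically competitive or historically interesting
alternates stay callable behind explicit switches:

* Maternal RBC volume defaults to the hematocrit identity
  $V_{rbc} = \frac{H}{1-H} V_{plas}$ (hematocrit as a fraction), which
  makes plasma volume, RBC volume and hematocrit mutually consistent to
  machine precision; the directly fitted logistic curve is
  `method = "logistic"`.
* Maternal kidney flow defaults to the cubic fitted to renal-flow data;
  the linear-transition form is `method = "transition"`.
* Maternal placental flow defaults to the proportional-to-volume model
  (constant 0.059176 L/h per mL, calibrated so term flow is 39 L/h); the
  linear-transition form is retained verbatim even though it
  under-predicts near term.
* Maternal GFR defaults to the quadratic; the 3/4-power allometric scaling
  from a 125 mL/min, 70 kg reference is `method = "allometric"`.
* Fetal hematocrit defaults to the cubic growth curve, which tracks the
  observed late-gestation plateau; the quadratic growth curve (the raw AIC
  winner by a sliver) is `form = "quadratic"`.
* Fetal brain and liver masses default to Gompertz curves; the cubic
  growth curves that scored the lowest AIC go negative in early gestation
  and are exposed as `variant = "lowest_aic"`.

For the fetal kidneys the coefficients printed alongside the published
curves are internally inconsistent (a Gompertz has one rate constant; the
printed display mixes two, and the printed power-law exponent belongs to a
different table row). We evaluate the maximum-likelihood table rows —
Gompertz $(6.3327\times 10^{-5}, 1.0409, 0.076435)$ and power law
$(0.016011, 0.91410)$ on fetal mass — which reproduce the reported
near-indistinguishability of the two fits (they agree within 2% at term).
The literal printed forms remain available via `as_printed = TRUE` for
anyone needing to reproduce the displayed equations exactly.

## Composite models

Quantities with no usable time-course data are built from the others:

* **Maternal rest-of-body volume** is a mass balance: fat-free-mass volume
  (density 1.1 kg/L, with the conceptus — fetal mass in g/1000, placenta
  and amniotic fluid scaled by densities 1.02 and 1.01 — removed from
  2 weeks onward) minus plasma, RBC and the six static compartment
  volumes. The static volumes are the non-pregnant body mass times female
  tissue percentages over densities.
* **Maternal regional flows** without time-course data interpolate the
  percent-of-cardiac-output linearly between the non-pregnant share at 0
  weeks and the near-term share, with "near term" fixed at 40 weeks.
* **Fetal arterial, lung and foramen ovale flows** follow from the three
  fitted sigmoids by flow conservation: `artb = lvtl + DA`,
  `lung = rvtl - DA`, `FO = artb - rvtl`.
* **Fetal organ flows** distribute the non-placental arterial flow using
  measured fetal shares for gut/kidneys/brain (6.8/5.4/14.3 of a
  non-placental total of 75) and adult shares for liver/thyroid (6.5/1.5
  of 54) applied to the remainder.
* **Rest-of-body flows** close the balance in both circulations.

Composites are evaluated lazily from their component functions rather than
as re-derived closed forms, so conservation identities hold to machine
precision by construction — and the test suite asserts them at $10^{-12}$
relative tolerance on a 0.1-week grid rather than trusting the
construction.

## Validity windows and gating

Three windows matter. Nothing conceptus- or fetus-related exists before
2 weeks (`pre_conception`); the conceptus volume curves are extrapolations
between 2 and 9 weeks, the age of the earliest calibration observation
(`extrapolated`); and the fetal composites rest on data with no
first-trimester observations, so they are flagged `pre_recommended` below
13 weeks. `evaluate_table()` returns raw values with per-cell flags by
default; `strict = TRUE` blanks `pre_conception`/`pre_recommended` cells so
exported tables cannot silently carry meaningless values. The fetal
rest-of-body volume is in fact negative until about 8 weeks, and the
ductus venosus curve exceeds the umbilical flow before 12 weeks — both
behaviours are documented consequences of extrapolating beyond the data,
not defects to be patched.

Ages outside [0, 42] weeks trigger a warning, not an error: tables over
the full modelled range must remain exportable, and one fitted sigmoid
(the right-ventricle curve) has its midpoint just past 42 weeks, which
tests legitimately probe.

## Calibration and selection

The calibration input is a `summary_dataset`: records of covariate, sample
mean $m_i$, sample SD $s_i$ and sample size $n_i$. Records missing $s_i$
or $n_i$ — typical of observations digitized from published figures — are
imputed with a 20% coefficient of variation and $n_i = 1$. Each record is
treated as $n_i$ Gaussian observations with mean $y(x_i;\theta)$ and known
variance $s_i^2$, for which $(m_i, s_i)$ are sufficient:

$$\ell(\theta) = \sum_i \left[ -\tfrac{n_i}{2}\log(2\pi s_i^2)
  - \frac{(n_i-1)s_i^2 + n_i\,(m_i - y(x_i;\theta))^2}{2 s_i^2} \right].$$

Only the quadratic term involves $\theta$, so the MLE coincides with
weighted least squares with weights $n_i/s_i^2$; the $\theta$-free terms
are kept so that log-likelihood magnitudes scale with the total number of
subjects, which is what makes reported AIC values comparable across
families fitted to the same data. The test suite verifies sufficiency
directly, by constructing raw samples with exactly the recorded mean and
SD and comparing likelihoods. A record with zero mean and no reported SD
would impute a zero variance and is rejected explicitly.

`fit_mle()` solves linear-in-parameter families exactly by weighted least
squares. Nonlinear families get a family-specific heuristic start (log-
scale profile regression for Gompertz, logit regression for logistic,
log-log regression for power laws; modified variants peel off the smallest
mean as a baseline first) plus Latin-hypercube perturbations of it,
each refined by Nelder-Mead and polished by BFGS; all randomness is
seeded, so fits are exactly reproducible. Non-convergence is reported in
the result, never silent.

`select_model()` ranks fits by AIC $= 2k - 2\ell$ and prefers the
lowest-AIC fit that never goes negative on the screening grid — by
default [0, 42] weeks at 0.1-week resolution, which resolves every
sign-crossing relevant here (the finest documented crossing is the
placenta curve's at 1.97 weeks). Fits within 0.1 AIC of each other are
treated as indistinguishable, with ties broken by nonnegativity, then
fewer parameters, then an age-based over a mass-based covariate (a
mass-based model needs an intermediate fetal-mass estimate at every
evaluation, so the age-based form is operationally simpler at equal
support). Mass-covariate candidates are screened through the composed
age-to-fetal-mass map so the screen is always an age interval.

## Synthetic data

`generate_summary_dataset()` draws, at each design age, `n` subject values
from a Gaussian centred on a known generating curve with SD equal to
either an absolute value or `cv` times the curve, then records mean, SD
and `n` — the exact structure the calibration engine consumes.
`generate_digitized_style()` emulates figure-extracted data: single draws
with no recorded spread, restored downstream by the 20%-CV imputation
rule. The default design (16 ages from 10 to 40 weeks every 2 weeks,
25 subjects per age, 10% CV) mirrors the visible spread and coverage of
the curated pregnancy datasets these models are built from; noise is
Gaussian on the natural scale, with an optional truncation at zero for
early-gestation designs where the noise is comparable to the curve.

What passing recovery tests on these data shows is that the engine finds
the maximum-likelihood fit and that the selection logic behaves as
specified under the assumed noise model. It does not show robustness to
features of real curated data that the generator deliberately omits:
between-study heterogeneity, non-Gaussian spread, covariate error in
gestational dating, or unequal covariate coverage.

## Numerical choices and test scale

* Feasibility screening and all grid-based assertions use inclusive
  0.1-week grids; extrema "during pregnancy" are taken over [0, 40].
* Recovery properties are measured over 50 seeds at the default design
  (median relative parameter error below 10%; the generating family beats
  linear growth on AIC in at least 45 of 50 replicates), with 5 optimizer
  starts per fit — enough for these well-initialized families, and the
  whole suite runs in well under a minute.
* The intercept of a sigmoid sampled only from 10 weeks onward is weakly
  identified: individual-seed estimates of $\theta_0$ can be off by
  ~15% even at the exact ML optimum. Recovery is therefore asserted on
  per-parameter *medians* across seeds and on curve-level agreement, not
  on single-seed parameter values.
* The two maternal RBC curves (direct logistic vs hematocrit identity)
  differ by up to 0.32 L around 20 weeks; the rest-of-body balance uses
  the direct logistic fit by default and both variants keep the composite
  inside its 31–34 L band.

## Known limitations

The repository describes averages for healthy, predominantly Caucasian,
singleton pregnancies and offers no population variability. Plasma volume
and hematocrit models fitted to aggregated data miss the late-pregnancy
plasma decline and hematocrit rise seen in longitudinal studies of
individuals. Fetal organ models tacitly assume functional organ systems at
early ages; below 13 weeks the composites should not be used. Placental
active transport is not described. The models are for humans only.
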