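# pregphys

Empirical models of maternal and fetal physiology during human pregnancy
and gestation, packaged as an evaluable, unit-aware library for
parameterizing physiologically based pharmacokinetic (PBPK) models.

Traditional PBPK models treat compartment volumes and blood flows as
constants. During the ~40 weeks between conception and birth almost none
of them are: maternal plasma volume rises ~50%, cardiac output climbs by a
third, the placenta and amniotic fluid appear from nothing, and the fetus
grows from microscopic to ~3.4 kg while running a circulatory system with
three shunts (ductus arteriosus, ductus venosus, foramen ovale) that have
no adult counterpart. `pregphys` provides, for every such quantity, a
closed-form curve in gestational age `t` (weeks):

* **Maternal**: body and adipose mass, plasma/RBC/placenta/amniotic-fluid
  volumes, static organ volumes, cardiac output, regional blood flows,
  hematocrit, glomerular filtration rate, and mass-balance/flow-
  conservation "rest of body" composites.
* **Fetal**: total and organ masses and volumes, ventricular and shunt
  flows, organ flows from measured flow fractions, hematocrit, and the
  rest-of-body composites.

The curve families are polynomials, Gompertz curves
`y = θ0·exp[(θ1/θ2)(1 − e^{−θ2 t})]`, logistics `y = θ0/(1 + e^{−θ1(t−θ2)})`
(plus "modified" variants with a baseline offset θ3) and allometric power
laws on body mass. The package also implements the machinery used to build
the repository: a Gaussian likelihood for summary-statistic data
(per-record mean, SD, sample size, with 20%-CV/n = 1 imputation for
digitized points), seeded multi-start maximum-likelihood fitting, AIC
scoring (`AIC = 2k − 2ℓ`), and model selection with a nonnegativity
feasibility screen — plus a synthetic summary-data generator so the whole
pipeline is testable end to end.

## Worked example

```r
library(pregphys)

evaluate_table(c("W^m", "V_plac^m", "Q_plac^m", "W^f", "Q_DA^f", "H^f"),
               0, 40, step = 10)
#>    t    W^m V_plac^m Q_plac^m        W^f   Q_DA^f    H^f
#> 1  0 61.103    0.000   0.0000 1.8282e-03   1.7231  0.000
#> 2 10 63.411   62.586   3.7036 6.4162e+00  10.3758 29.251
#> 3 20 68.539  239.464  14.1705 2.7500e+02  60.1539 37.587
#> 4 30 73.475  461.376  27.3024 1.5511e+03 287.2209 41.068
#> 5 40 75.206  659.064  39.0008 3.4396e+03 759.9110 55.754
```

Reading the term row: the mother weighs 75.2 kg (fetus included), her
placenta holds 659 mL and receives 39 L/h of maternal blood, the fetus
weighs 3440 g, 760 mL/min of fetal blood bypasses the lungs through the
ductus arteriosus, and fetal hematocrit is 55.8%. Columns carry their
units (`attr(tab, "units")`) and per-cell validity flags — conceptus
quantities are flagged before 2 weeks (pre-conception) and fetal
composites before 13 weeks (no first-trimester calibration data);
`strict = TRUE` blanks such cells.

The fetal shunt flows close exactly by construction:

```r
round(fetal_heart_flows(c(20, 40)), 1)
#>    t  rvtl  lvtl    DA   artb  lung    FO
#> 1 20  77.5  48.6  60.2  108.8  17.3  31.3
#> 2 40 953.8 453.0 759.9 1213.0 193.9 259.1
```

at every age `artb = lvtl + DA`, `lung = rvtl − DA`, `FO = artb − rvtl`.

Refitting a family to data and selecting a model:

```r
spec <- model_spec("gompertz", c(0.0018282, 1.1735, 0.077577))  # fetal mass
dat  <- generate_summary_dataset(spec, sampling_design(seed = 17))
fits <- list(fit_mle("gompertz", dat, seed = 17),
             fit_mle("cubic_growth", dat, seed = 17))
select_model(fits)   # lowest-AIC fit that never goes negative on [0, 42]
```

A command-line wrapper with `evaluate`, `fit`, `simulate` and `check`
subcommands is installed under `exec/` (see `system.file("exec", "pregphys",
package = "pregphys")`).

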