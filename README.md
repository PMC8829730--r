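# poisfl

Poisson regression for sparse count data when the maximum likelihood
estimate does not exist.

## The problem

Epidemiologists and biostatisticians model event counts with log-linear
Poisson regression,

    log mu_i = x_i' beta + z_i,      y_i ~ Poisson(mu_i),

where `z_i` is a log-offset (persons tested, follow-up time, a rate
multiplier) and `exp(beta_j)` is an incidence rate ratio (IRR). With rare
events the ML estimate can fail to exist — the data are *separated*
whenever some direction `gamma != 0` satisfies `x_i'gamma = 0` on every row
with events and `x_i'gamma <= 0` on every event-free row. The textbook case
is a category with zero events: the rate ratio against it divides by zero,
`glm()` "converges" to a perfect fit of the zeros with exploding
coefficients, and Wald intervals collapse.

`poisfl` provides, behind one small data container (`pois_data`):

| method | function | point estimates | predictions | under separation |
|---|---|---|---|---|
| maximum likelihood | `fit_ml()` | biased in sparse data | `sum(mu) = sum(y)` | do not exist (last iterate returned, flagged) |
| Firth penalization (FL) | `fit_fl()` | bias-reduced | overpredict by `(k+1)/2` events | finite |
| FL + intercept correction (FLIC) | `fit_flic()` | FL slopes | `sum(mu) = sum(y)` | finite |
| FL + added covariate (FLAC) | `fit_flac()` | = FLIC for Poisson | `sum(mu) = sum(y)` | finite |
| Bayesian data augmentation (BDA) | `fit_bda()` | max-posterior (ridge) | `sum(mu) = sum(y)` | finite |
| exact conditional Poisson | `exact_poisson()` | MCLE / median-unbiased | none | finite (MUE) |

plus `detect_separation()` (linear-programming certificate),
`wald_ci()` / `profile_ci()` (Wald, profile likelihood, profile *penalized*
likelihood), and a scenario simulator (`scenario_config()`,
`run_scenario()`) for events-per-variable method comparisons.

## Worked example

The Austrian COVID-19 occupational testing series (March 2020): 0 positives
among 352 supermarket employees, 3/444 in nursing homes, 3/365 in
hospitals.

```r
library(poisfl)
covid <- pois_data(y = c(0, 3, 3),
                   x = cbind(nursing = c(0, 1, 0), hospital = c(0, 0, 1)),
                   multiplier = c(352, 444, 365))

detect_separation(covid)
#> Separation detected: ML estimate does not exist.
#> certificate direction gamma*: -1  1  1
#> strictly separated event-free rows: 1

fl <- fit_fl(covid)
fl
#> Poisson regression (FL)
#>             estimate    IRR     se
#> (Intercept)  -6.5568 0.0014 1.4142
#> nursing       1.7137 5.5495 1.5119
#> hospital      1.9096 6.7507 1.5119
#> logLik: -3.56694  penalized: -2.66075
#> NOTE: data are separated; ML estimates do not exist

exp(profile_ci(fl, parm = 2:3))   # IRR scale
#> 95% CI (ppl):
#>           lower    upper
#> nursing  0.5383 746.1534
#> hospital 0.6548 907.6496

exact_poisson(covid, j = 2)
#> Exact conditional Poisson inference
#>   MUE (IRR): 3.0501
#>   exact 95% CI (IRR): (0.3276, Inf)
#>   mid-p 95% CI (IRR): (0.4624, Inf)
```

Reading the output: no supermarket employee tested positive, so ML cannot
estimate the rate ratios at all (the certificate `(-1, 1, 1)` says
"multiply the supermarket indicator by -1"). Firth penalization gives
finite rate ratios — nursing-home staff 5.55, hospital staff 6.75 times the
supermarket infection rate — but the penalized-profile intervals stretch
to IRR ~750-900, showing how little the 6 events actually pin down.
The exact conditional analysis conditions away the intercept and gives a
median-unbiased rate ratio of 3.05 with a one-sided interval (0.46, Inf):
the data cannot bound the ratio from above.

A command-line interface mirrors the R API:

```sh
poisfl fit --input covid.csv --outcome positive --multiplier tested --method fl
poisfl diagnose --input covid.csv --outcome positive
poisfl simulate --k 2 --epv 3 --beta1 -1.386 --reps 500 --seed 1
```

## Layout

- `R/` — implementation; `tests/testthat/` — unit, property and acceptance
  tests (`test-acceptance.R` holds the acceptance criteria).
- `vignettes/sparse-poisson-methods.Rmd` — the methods vignette: models,
  assumptions, numerical choices, and what the simulation generator does
  and does not emulate.
- `inst/extdata/` — the COVID table and the simulator's latent correlation
  structure as plain CSV.
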