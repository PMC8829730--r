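---
title: "Poisson regression when the ML estimate does not exist: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Poisson regression when the ML estimate does not exist}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poisfl)
```

## The model and the separation problem

`poisfl` fits log-linear Poisson models for event counts,

$$\log \mu_i = x_{i\cdot}\beta + z_i, \qquad y_i \sim \mathrm{Poisson}(\mu_i),$$

where $z_i$ is a known offset — the log of an exposure such as persons
tested, follow-up time, or a rate multiplier — and $\exp(\beta_j)$ is an
incidence rate ratio (IRR). With rare events the maximum likelihood (ML)
estimate can fail to exist: whenever a nonzero direction $\gamma$ satisfies
$x_{i\cdot}\gamma = 0$ for every row with $y_i > 0$ and
$x_{i\cdot}\gamma \le 0$ for every event-free row (strictly for at least
one), the likelihood increases without bound along $\beta + t\gamma$ and the
fitted means of the strictly-separated zero rows are driven to 0. We call
such data *separated*. The canonical instance is a category with no events:
in the Austrian COVID-19 occupational testing series (0 positives among 352
supermarket employees, 3/444 in nursing homes, 3/365 in hospitals) the risk
ratio against supermarkets is formally $3/365 \div 0/352$.

Notably, the verdict depends only on the pattern of zero counts and on the
design matrix — never on the offsets or on how large the positive counts
are — and adding covariates can only create, never remove, separation.

`detect_separation()` decides the condition exactly. The direction $\gamma$
is restricted to the null space of the event rows, and the sum of
$-x_{i\cdot}\gamma$ over event-free rows is maximized subject to
$x_{i\cdot}\gamma \le 0$ and the box $|\gamma_j| \le 1$ (the condition is
scale-invariant, so the box only bounds the program). A strictly positive
optimum yields a certificate $\gamma^*$ that is returned with the verdict.
Since no linear-programming solver is available as a dependency, the
program is solved by a small dense simplex with Bland's rule; the
substitution $\gamma = u - w$, $u, w \in [0,1]$ makes all right-hand sides
nonnegative so no phase-1 is needed, and Bland's rule guarantees
termination under the heavy degeneracy of the zero right-hand sides.

`fit_ml()` deliberately does not abort on separated data: it returns the
last Newton iterate flagged `separated = TRUE`, because the behaviour of
standard software at "the last iteration" is itself an object of study in
sparse-data method comparisons.

## Firth penalization and its prediction-debiased variants

`fit_fl()` maximizes the Jeffreys-prior penalized likelihood

$$\ell^*(\beta) = \ell(\beta) + \tfrac12 \log |I(\beta)|,
\qquad I(\beta) = X'WX,\; W = \mathrm{diag}(\mu_i),$$

whose gradient is exactly the modified score
$U_j^*(\beta) = \sum_i x_{ij}(y_i + h_i/2 - \mu_i)$ with $h_i$ the
leverages (diagonals of $W^{1/2}X(X'WX)^{-1}X'W^{1/2}$). Equivalently, FL
is ML on counts augmented by half the leverages, with the leverages
recomputed at every iteration rather than fixed once — this is what makes
the iteration converge to the exact root of $U^*$ and hence to the
maximizer of $\ell^*$, and the package tests verify the two routes agree.
The estimate exists and is finite under separation, and it removes the
leading $O(n^{-1})$ bias of ML.

The intercept equation of $U^*$ implies a conservation identity with a
drawback: $\sum_i \hat\mu_i = \sum_i y_i + (k+1)/2$, i.e. FL systematically
overpredicts the event total by half the number of parameters. Two
modifications repair this:

* **FLIC** (`fit_flic()`) keeps the FL slopes and shifts the intercept by
  $\delta = \log(\sum y / \sum \hat\mu_{FL})$, the closed-form ML solution
  of a one-parameter Poisson regression on the FL linear predictor as
  offset. By the conservation identity,
  $\delta = \log\{\sum y / (\sum y + (k+1)/2)\}$ exactly.
* **FLAC** (`fit_flac()`) adds one pseudo-observation per row with count
  $h_i/2$ (same covariates and offset as its source row) plus an indicator
  covariate $G$ separating pseudo from original rows, then fits ordinary
  ML; predictions set $G = 0$.

For Poisson models — unlike logistic — FLIC and FLAC coincide coefficient
by coefficient; the package asserts this identity to $10^{-7}$ on random
instances rather than assuming it. Note that the FLIC step is a Poisson,
not a logistic, recalibration: the one-parameter intercept correction of a
log-linear rate model has the closed form above, which a logistic
recalibration would not reproduce.

## Confidence intervals

Wald intervals (`wald_ci()`) are reported for completeness but collapse or
become meaningless under separation. The reference method for Firth-type
fits is the profile *penalized* likelihood (PPL) interval
(`profile_ci(mode = "ppl")`): the set of $\beta_j^*$ with

$$2\,[\ell^*(\hat\beta) - \max_{\beta_{-j}} \ell^*(\beta_j^*, \beta_{-j})]
  \le \chi^2_1(1-\alpha),$$

with the leverages recomputed inside every inner maximization. A cheaper
approximation (`mode = "pl_fixed"`) profiles the ordinary likelihood of the
augmented data with pseudo-counts frozen at the FL solution; it gives
slightly narrower intervals on non-saturated data (checked as a width
inequality in the tests) and is exact for saturated designs, where $h
\equiv 1$ at every $\beta$. Bounds are located by doubling-step bracketing
from the estimate followed by root-finding on the profile deviance; a
profile that never crosses the cutoff before $|\beta_j| = 40$ on the log
scale is reported as an infinite bound — printed IRR bounds in the
worked examples reach $\sim 900$ ($\log \approx 6.8$), so 40 is far beyond
any finite-data bound while still detecting genuinely one-sided profiles.
The $\chi^2_1$ cutoff is computed with `qchisq()`, not hard-coded, and
PPL intervals are allowed to be asymmetric — that asymmetry is the signal
that Wald intervals are inadequate.

## Bayesian data augmentation

`fit_bda()` implements the Sullivan–Greenland device: a mean-zero normal
prior with variance $v$ on a log-IRR is encoded as one pseudo-observation
with covariate value $1/S$, event count $S^2/v$ and offset $\log(S^2/v)$,
zero in every other column *including the intercept*. Its log-likelihood
contribution is $-\beta_j^2/(2v) + O(1/S)$, so ML on the augmented data is
maximum-posterior (ridge) estimation; the tests verify agreement with a
generic ridge optimizer to $10^{-4}$ at $S = 10^4$. Because the intercept
column of every pseudo-row is 0, the intercept score — and hence the exact
prediction conservation $\sum \hat\mu_i = \sum y_i$ over original rows —
is untouched.

Choices made here:

* $v$ is computed from the unrounded prior SE $(\log U / 1.96)^2$; the
  rounded value 12.39 sometimes quoted for $U = 1000$ corresponds to
  rounding the SE to 3.52 first.
* With $S = 10^4$ the profile-likelihood CI of the *encoded prior alone*
  reproduces $\pm 1.96\sqrt v$ to about $10^{-3}$ — that is the sense in
  which the encoding is "symmetric to the third decimal". A BDA CI on
  actual sparse data is generally asymmetric, since the data contribute an
  asymmetric likelihood; the acceptance suite tests the former property and
  the finiteness/conservation properties of the latter.
* Default priors follow the simulation design: IRR interval $(1/1000,
  1000)$ for binary/ordinal covariates, $(1/100, 100)$ for continuous ones.
* Priors not centered at IRR 1 are out of scope and rejected.
* BDA intervals profile the full augmented likelihood, i.e. the other
  pseudo-observations stay in the model while one coefficient is profiled.

## Exact conditional inference

For one target coefficient, `conditional_support()` enumerates the exact
conditional distribution of its sufficient statistic
$T_j = \sum_i x_{ij} y_i$ given the observed sufficient statistics of all
other coefficients (including the total event count, the intercept's
statistic). The weights $c(t)$ accumulate $\prod_i E_i^{y_i}/y_i!$
($E_i = e^{z_i}$) over all outcome vectors matching the nuisance
statistics, by depth-first recursion over rows with memoization on the
remaining statistic budgets and log-sum-exp accumulation. Pruning uses the
fact that a remaining budget of $b$ events over the suffix rows moves each
nuisance statistic by an amount in $[b\min_r v_r, b\max_r v_r]$.

Design decisions:

* **Integer covariates only.** Conditioning on a continuous covariate
  forces a singleton support (the observed outcome is the only one
  matching the statistic), from which no inference is possible; such
  columns are rejected with a clear error rather than silently producing a
  degenerate result.
* **Feasibility guards** $\sum y \le 60$, $n \le 250$, $k \le 5$ bound the
  enumeration to the regime where exact conditional Poisson inference is
  practical at all.
* The MCLE solves $E_\beta[T] = t_{obs}$ and fails to exist exactly when
  $t_{obs}$ sits on the support boundary; the MUE then solves the
  half-median tail equation $P(T \ge t_{obs}) = 0.5$ (or its mirror). For
  interior $t_{obs}$ the MUE is the midpoint of the two half-median
  solutions (Hirji-style convention — the boundary fallback is standard,
  the interior convention had to be chosen).
* CIs invert the tail equations $P(T \ge t_{obs} | \beta) = \alpha/2$
  (exact) or $P(T > t_{obs}) + \tfrac12 P(T = t_{obs}) = \alpha/2$
  (mid-p); both are exposed because published lower limits for the COVID
  table (0.46, 0.56) solve the mid-p/one-sided equation $p^3 = 0.05$, not
  the two-sided exact equation $p^3 = 0.025$ (which gives $\approx 0.33$).
  Which convention a given software's "exact CI" label means is not always
  documented; `exact_poisson()` reports both.
* All tail-equation roots are found by bisection on the log-IRR scale in
  $[-40, 40]$ with tolerance $10^{-8}$, using log-sum-exp throughout.

## The simulation engine: what the stated world is

`scenario_config()` / `run_scenario()` reproduce a realistic sparse-event
factorial design: $k \in \{2,5,10\}$ covariates (the first $k$ of a fixed
battery of four binary, two ordinal and four continuous covariates derived
from a correlated Gaussian copula), events-per-variable ratio
$\mathrm{EPV} \in \{3,5,10\}$ fixing $n = \mathrm{EPV}\cdot k / 0.1$, and
a grid of true effects $\beta_1$ for the rare binary covariate $x_1$
($P(x_1 = 1) = 0.1$). Remaining coefficients are fixed
($\pm 0.69, \pm 0.35$; continuous effects $\pm 0.69/\mathrm{ISR}$ scaled by
the intersextile range so a 1/6-to-5/6 quantile shift has a comparable
rate effect). Each row carries a zero-truncated Poisson rate multiplier
entering as an offset.

Conventions chosen where the design is stated loosely:

* "Zero-truncated Poisson with mean 1.6" is read as underlying Poisson
  parameter 1.6 truncated to $\ge 1$ (truncated mean $\approx 2.0$); the
  alternative reading (truncated mean $= 1.6$) is available via
  `psi_mode = "truncated"`.
* The marginal incidence 0.1 is per row *including* the multiplier — only
  then do the design's published sizes ($n = 60$ at $k=2$,
  $\mathrm{EPV}=3$; $n = 250$ at $k=5$, $\mathrm{EPV}=5$) satisfy
  $n = \mathrm{EPV}\cdot k/0.1$.
* The two log-normal latents are truncated at their 99th percentile via the
  copula-preserving inverse-CDF map $z \mapsto \Phi^{-1}(0.99\,\Phi(z))$ —
  a truncated *distribution*, not a clamped transformation, and one that
  preserves the latent correlation structure.
* The intercept is calibrated in closed form,
  $\beta_0 = \log(0.1) - \log \widehat E[e^{x\beta}\psi]$, on a large
  calibration sample drawn with a seed fixed per scenario, so coefficients
  and ISRs are deterministic across replicates.
* Unlisted latent correlations are 0 and the matrix is checked for
  positive definiteness at load.

The generator emulates the *distributional shape* of sparse epidemiological
data — rare correlated binaries, skewed exposures, a controlled event
budget. It does not emulate overdispersion, zero inflation, measurement
error, or informative exposure; a green simulation test therefore
establishes the comparative behaviour of the estimators under the stated
Poisson world, not their robustness outside it. Published figure values
from large simulation studies are not desk-reproducible; the test suite
instead verifies the qualitative findings at reduced replicate counts
(500 instead of 10,000, noted in the acceptance suite): penalized and
Bayesian fits always finite where ML separates, FLAC at least as accurate
as FL for prediction (FL's overprediction is exactly $(k+1)/2$ events),
FL's $\beta_1$ bias toward zero where ML diverges negative.

## Numerical choices

* Newton with step-halving; start at
  $(\log(\sum y/\sum e^z), 0, \dots, 0)$; converge when the largest
  (modified) score component is below $10^{-6}$ *and* the step norm is
  below $10^{-8}$; 100 iterations cap. Once the score is below $10^{-3}$
  full Newton steps are accepted without the ascent check, which otherwise
  drowns in floating-point noise when the objective is of order $10^9$
  (BDA pseudo-counts). BDA additionally tightens the score tolerance to
  $10^{-10}\sum y$ so the conservation identity holds to $10^{-8}$
  relative.
* The penalized-likelihood "hat" computation uses the symmetric form
  $W^{1/2}X(X'WX)^{-1}X'W^{1/2}$, which satisfies
  $\mathrm{tr}(H) = k+1$ (a frequently mistyped formula elsewhere omits a
  transpose).
* The log-likelihood keeps the $-\log(y_i!)$ constant (as `lgamma(y+1)`,
  valid for the fractional pseudo-counts of augmented data) so values are
  comparable across methods.
* Counts must be integers at the user boundary; fractional counts exist
  only inside augmented representations.
* Rank-deficient designs are an error for all fitters; the separation
  detector tolerates them by restricting the certificate to the column
  space (a declared convention — separation theory for rank-deficient
  designs is not settled).

## Known limitations

* No overdispersion (quasi-Poisson/negative binomial), zero-inflated or
  hurdle extensions, and no sandwich covariances.
* Exact conditional inference provides no intercept estimate and hence no
  predictions, and is limited by the enumeration guards.
* The FLIC/FLAC covariance is taken from the corresponding fit's
  information matrix; inference should use the profile methods, not Wald,
  whenever the data are sparse enough for the choice to matter.
* `run_scenario()` computes CIs only on request; coverage/power columns
  are `NA` otherwise.
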