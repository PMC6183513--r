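---
title: "Estimating natural and bycatch mortality-at-age from strandings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating natural and bycatch mortality-at-age from strandings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strandmort)
```

## The problem

Stranding records are, for most cetacean populations, the only window on
demography: each carcass contributes one age at death. Under the working
assumption of a stationary age structure, the age distribution of deaths
identifies mortality-at-age. Classical tools — the cohort life table and
the Siler competing-risk hazard — recover *total* mortality, but
management needs the split between natural mortality and mortality caused
by fisheries bycatch. This package estimates that split from the age
structure alone, by letting a dedicated "accident hump" component of an
adapted Heligman-Pollard (aHP) curve absorb the mortality concentrated at
the ages bycatch strikes, while smooth infant-decline and adult-rise
components absorb the natural schedule.

## Life tables

`life_table` bins ages by truncation to whole years (growth-layer ages
are read as integers), counts deaths `N(x)`, and derives the standing
cohort `S(x)`, survivorship `l(x)`, death proportions `d(x)`, death
probabilities `q(x) = N(x)/S(x)` and life expectancies `e(x)`. Three
conventions, stated because the data source does not fix them:

* **Person-years**: `L(x) = (l(x) + l(x+1))/2`, i.e. deaths halfway
  through the interval — standard cohort practice; it forces
  `e(omega) = 0.5`.
* **Cohort closure**: `q = 1` at the oldest observed class, so that
  `sum d(x) = 1` exactly.
* **Radix**: cosmetic; it scales `S` only, every proportion is
  radix-free.

`life_table_from_qx` inverts a model schedule into the same table
(appending a closing class if the schedule ends below 1), and
`cumulative_survival` exposes the bare recursion
`l(x+1) = l(x)(1 - q(x))` needed by the Leslie module.

## The Siler model

Five non-negative parameters, hazard
`mu(x) = a1 exp(-b1 x) + a2 + a3 exp(b3 x)`, survivorship the product of
the three component survivorships (with the `b -> 0` limits handled
analytically). The fit (`fit_siler`) maximises the multinomial likelihood
of the observed age-class counts under the discrete age-at-death
distribution `f(x) = l(x) - l(x+1)` with terminal mass `l(max_age)`.
Deaths data are a census of ages at death, so the multinomial is the
natural objective; a least-squares alternative on log death probabilities
is kept behind `objective = "leastsquares"` for schedules derived from
life-table rates. Parameters are optimised on the log scale
(unconstrained Nelder-Mead, positivity by construction) from a fixed
default start `(0.1, 0.5, 0.05, 0.01, 0.1)` plus ten seeded jittered
restarts, each polished by a second simplex run.

Young carcasses are under-represented in stranding records (predation,
faster decomposition, lower detection). The `rm` argument removes the
leading age classes from the objective — the distribution is renormalised
over the retained classes — while predictions remain available for all
ages. On synthetic records with half the age-0 and age-1 animals deleted,
the `rm = 2` fit recovers the true juvenile `q` substantially better than
the naive fit (this is a test in the suite).

## The adapted Heligman-Pollard model

\[
q(x) = A^{(x+B)^C} + \left\{ I + D e^{-E\,(\ln x/F)^2} \right\}
      + \frac{G H^x}{1 + G H^x}
\]

`A` sets the infant mortality level, `B` (yr) shifts and `C` shapes its
decline; `D`, `E` and `F` (yr) are the severity, spread and location of
the lognormal accident hump; `G` and `H` set the level and rate of the
logistic adult rise. The ninth parameter `I` lifts the hump baseline so
that the anthropogenic component need not vanish at age 0. Natural
mortality is defined as infant + adult terms, anthropogenic mortality as
the hump (including `I`); the decomposition is additive by construction.

Numerical conventions:

* **Age-class evaluation of the hump.** During fitting and class-level
  prediction the hump term is evaluated at the class midpoint `x + 0.5`,
  so `ln(x/F)` is defined at age class 0 — which is precisely where `I`
  matters. `ahp_qx` called directly evaluates at the ages given (so the
  hump equals `I + D` exactly at `x = F`).
* **Likelihood.** Binomial per age class: deaths `M(x)` out of the
  at-risk `S(x)` from the cumulative survival of the observed cohort,
  with success probability the model `q(x)`. Parameter vectors whose
  `q(x)` leaves `(0, 1)` at any required age score `-Inf` instead of
  raising, so the sampler simply discards them.
* **The terminal class is dropped when cohort-closed.** If everyone
  still at risk at the oldest class dies there (`M = S`, as cohort
  closure forces), that class is open-ended: the model's probability of
  *eventual* death is 1 regardless of the parameters, so the class
  carries no information about the one-year `q`. Scoring the model's
  `q(omega)` against it would penalise every candidate by hundreds of
  log-units and drag all nine parameters toward an artefactual mode —
  measurably so on simulated data, where the generating parameters only
  sit at the likelihood maximum once the class is excluded.

### Bayesian melding with IMIS

Priors are independent uniforms on a box (`ahp_priors`); the defaults are
deliberately wide and should be narrowed with biological knowledge in
real analyses. Collapsed bounds (`lower = upper`) fix a parameter, which
is how reduced models are expressed. The posterior is explored by
incremental mixture importance sampling with an optimizer stage, with the
published defaults: 10 optimizer starts, up to 10 IMIS iterations, a
500-row final resample, 90% credible intervals, and early stopping once
the expected unique fraction of the resample reaches `1 - 1/e = 0.632`
(computed exactly as `sum_i [1 - (1 - w_i)^K]/K`).

Design choices where the recipe leaves room, made once and kept:

* **Logit-box coordinates.** The sampler works on
  `u = logit((x - lower)/width)`, where the uniform prior becomes a
  product of standard logistic densities. Mixture clouds can then never
  leave the support, and parameters spanning orders of magnitude (`G`
  runs from 1e-6 to 0.1 in the default box) are far closer to Gaussian.
* **Optimizer stage.** Nelder-Mead (max 1000 evaluations, one restart
  from the incumbent — a fresh simplex escapes the premature shrinkage
  the method is prone to in nine dimensions) from the `n_opt` highest-
  likelihood prior points, spaced so consecutive starts never share a
  nearest-neighbour ball. Runs that beat the best prior-pool likelihood
  seed a Gaussian cloud whose covariance is the inverse numerical Hessian
  at the optimum (central differences; eigenvalues floored at 1e-8 and
  capped at 9 logit-units² so flat ridge directions cannot blow the cloud
  up; inflated 1.2x), with the neighbourhood covariance as fallback.
* **Incremental components.** Each IMIS iteration centres a component at
  the current highest-weight point (ties broken by pool index) and uses
  the importance-weighted covariance of its `pool/n_opt` nearest
  neighbours, weights shrunk towards uniform (`(w_i + 1/n)/2`), inflated
  1.2x. The weighting stretches the component along whatever posterior
  ridge the neighbourhood traces; with unweighted neighbours the envelope
  repeatedly collapsed onto a handful of points on this model's curved
  ridges.
* **Envelope.** `g(u) = (N0 p(u) + sum_k n_k phi_k(u)) / (N0 + sum n_k)`;
  weights `w ∝ p L / g`, normalised by log-sum-exp.
* **Determinism.** Every stochastic stage draws from a named substream
  of the single user seed (priors / optimizer / each cloud / resample),
  so runs are bit-reproducible and stages are decoupled.

The nine-parameter posterior is genuinely ridge-shaped — several
parameterisations produce near-identical curves — so parameter marginals
can be wide and multimodal while the *curve* posterior is tight. All
quality checks in the suite are therefore phrased at the curve level
(band coverage, hump location), plus a reduced three-free-parameter model
whose posterior means are checked against dense grid quadrature.

## Leslie matrices

`leslie_matrix` uses a post-breeding birth-pulse census: survival
`P_i = 1 - q(i)` on the subdiagonal and fertilities
`F_i = P_i * sex_ratio * m[i+1]` on the top row (calves appear at the
end of a time step to mothers counted at its start; last-class fertility
0; only female offspring counted). `eigen_analysis` reports the Perron
root λ and `r = ln λ`, the stable age distribution, reproductive values
(`v_0 = 1`), sensitivities `v_i w_j / <v, w>`, elasticities
`(a_ij/λ) s_ij` (which sum to 1), net production `R0 = sum l(x) F_x` and
generation time `ln(R0)/ln(λ)` with the cohort formula
`sum x l(x) F_x / R0` as the `λ = 1` fallback. Trailing classes that are
both sterile and unreachable are trimmed before the decomposition (they
make the matrix reducible) and the reported vectors padded back with
zeros; a fully sterile schedule returns `λ = 0` with `r = -Inf` rather
than an error. A dominant eigenvalue with non-negligible imaginary part
raises "no Perron root".

## The synthetic-data generator

`scenario_spec` emulates the structure of a coastal bottlenose-dolphin
stranding record: by default 220 natural deaths from a Siler schedule
(`a1 = 0.25, b1 = 0.6, a2 = 0.01, a3 = 0.002, b3 = 0.18`, oldest class
30 — a plausible small-cetacean schedule with a few percent of the cohort
reaching the terminal class) plus 80 bycaught animals whose ages are a
truncated normal on `[0, max_age]` with mean 3 yr and SD 1.5 yr — mode
before maturity — rounded to whole years. Optional per-age retention
probabilities thin the young classes to mimic carcass loss. Cause labels
are carried in the output for diagnostics but never given to the
estimators. `scenario_truth` returns the exact mixture `q(x)` for
recovery checks; thinning is deliberately not reflected there, since it
biases the observed record, not the underlying mortality.

Two things the generator does not emulate: age-reading error, and
non-stationary age structure (a growing or shrinking population violates
the equilibrium assumption shared by all estimators here). Passing tests
therefore demonstrate correct recovery under the model's own assumptions,
not robustness to their failure.

The mixture scenario is also intentionally *misspecified* with respect to
the aHP curve — a Siler-plus-normal-hump `q(x)` is not exactly an aHP
`q(x)`. With large samples the aHP's credible bands become narrower than
that structural bias, so band-coverage checks use `simulate_ahp`, which
draws ages from a known aHP schedule (the well-specified case); hump-
location recovery is checked on both generators.

## Problem sizes and runtime choices

The test suite fits the aHP at prior pools of 800-5000 draws and samples
of 200-3000 records (a fit takes a few seconds), uses a 60³ grid for the
reduced-model quadrature oracle, 10⁵-10⁶ draws for distributional checks,
and 500-year projections for eigenvalue-convergence checks. These sizes
were chosen so each check is decisive for its tolerance while the whole
suite stays fast.

## Known limitations

* Equilibrium age structure is assumed throughout; trends in abundance
  bias all schedules.
* The aHP is over-parameterised for records with few age classes;
  informative priors are then essential (the bounds are the instrument
  for that — non-uniform priors are not implemented).
* Credible bands reflect sampling uncertainty given the model; they do
  not include age-reading error or model misspecification.
* Density dependence is outside scope: Leslie projections use static
  vital rates, so long sustained growth or decline should be read as a
  pressure indicator, not a forecast.
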