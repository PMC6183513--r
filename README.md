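# strandmort

Estimating total, natural and anthropogenic (bycatch) mortality-at-age of
cetaceans **using only the age structure of stranded animals**.

For many cetacean populations, stranding records — dead animals found
ashore whose age is read from tooth growth layers — are the only source of
demographic information, and fishery bycatch is the dominant human-caused
threat. Total mortality-at-age can be estimated from such records with
classical tools (life tables, the Siler competing-risk model), but those
cannot separate natural from anthropogenic deaths. `strandmort` implements
an age-structured framework that does, without requiring cause-of-death or
fishery observer data, and projects the demographic consequences of the
estimated mortality. It is aimed at marine-mammal ecologists and managers
working with stranding networks.

## Models

**Siler competing-risk model** (5 parameters). The hazard is the sum of a
declining juvenile risk, a constant risk and a rising senescent risk:

    mu(x) = a1 exp(-b1 x) + a2 + a3 exp(b3 x)

with survivorship `l(x) = l_j(x) l_c(x) l_s(x)`. Fitted to ages at death
by multinomial maximum likelihood (`fit_siler`), with an option to exclude
under-represented young age classes from the objective while still
predicting them.

**Adapted Heligman-Pollard model** (9 parameters). The probability of
dying in `[x, x+1)` is three additive components — infant decline,
lognormal "accident hump", logistic adult rise:

    q(x) = A^((x+B)^C)  +  { I + D exp[-E (ln(x/F))^2] }  +  G H^x / (1 + G H^x)

The hump captures mortality concentrated at particular ages (here,
bycatch); the ninth parameter `I` lifts its baseline so bycatch at age 0
need not be zero. Natural mortality is the infant + adult terms,
anthropogenic mortality the hump. The model is fitted by **Bayesian
melding with Incremental Mixture Importance Sampling** (`fit_ahp`):
uniform box priors, a binomial deaths-given-at-risk likelihood, an
optimizer stage seeding Gaussian mixture components at posterior modes,
incremental components at high-weight points, and a final weighted
resample (500 draws by default) once the expected unique fraction reaches
1 − 1/e. Pointwise 90% credible bands for each mortality component come
from `predict_ahp`.

**Leslie matrix demography.** `leslie_matrix` builds the female-based
projection matrix from any `q(x)` schedule and a maternity schedule
(post-breeding census, user-set birth sex ratio); `leslie_project`
iterates `N(t+1) = A N(t)` (100 years by default); `eigen_analysis`
returns the annual growth rate λ (dominant eigenvalue), stable age
distribution, reproductive values, sensitivities/elasticities, net
production `R0` and generation time.

A synthetic-data module (`scenario_spec`, `simulate_strandings`,
`simulate_ahp`) generates stranding records with known ground truth —
Siler natural deaths plus a normally distributed bycatch hump with mode
before maturity, optionally thinned at young ages — so every estimator is
testable without real data.

## Worked example

Simulate a stranding record of 220 natural deaths plus 80 bycaught
dolphins (hump centred at age 3), then estimate and decompose mortality:

```r
library(strandmort)

sample <- simulate_strandings(scenario_spec(seed = 1))
sample
#> Ages at death: 300 records, range 0 - 30 years
#>         anthropogenic       natural
#>                    80           220

fit_siler(sample, seed = 1)$par        # total mortality only
#>      a1      b1      a2      a3      b3
#> 0.19073 0.20888 0.00000 0.00184 0.17887

post <- fit_ahp(sample, ahp_priors(draws = 5000), seed = 1)
post
#> aHP posterior (Bayesian melding with IMIS)
#>   resample: 500 rows; pool: 12000; IMIS iterations: 4
#>   expected unique fraction: 0.637 (stop threshold 0.632)

head(subset(predict_ahp(post, 0:30), component == "anthropogenic"), 5)
#>   age     component        lower      median      upper
#>     0 anthropogenic 0.0006639581 0.006712742 0.02484358
#>     1 anthropogenic 0.0010183885 0.008280660 0.02730647
#>     2 anthropogenic 0.0057320719 0.023709634 0.06227867
#>     3 anthropogenic 0.0311881731 0.064782511 0.11130163
#>     4 anthropogenic 0.0441212527 0.079629258 0.11760310
```

The estimated bycatch component peaks near the injected hump age (3 yr)
and is near zero at birth, with 90% credible bands. Projecting two Leslie
matrices from the posterior-median schedules — natural-only versus total
mortality — quantifies what bycatch costs the population:

```r
m  <- default_maternity(30)
qn <- subset(predict_ahp(post, 0:30), component == "natural")$median
qt <- subset(predict_ahp(post, 0:30), component == "total")$median
eigen_analysis(leslie_matrix(pmin(qn, 1), m))$lambda   # 1.0078  (+0.8 %/yr)
eigen_analysis(leslie_matrix(pmin(qt, 1), m))$lambda   # 0.9838  (-1.6 %/yr)
```

Under natural mortality alone the population grows slightly; with the
estimated bycatch added it declines — the comparison managers need to set
bycatch limits.

The same workflow runs from the shell:

```sh
Rscript inst/cli/strandmort.R run --seed 1 --out-dir results/
Rscript inst/cli/strandmort.R simulate --seed 3 --out ages.csv
Rscript inst/cli/strandmort.R siler --input ages.csv --out schedule.csv
```

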