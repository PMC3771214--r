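# socialval

Hierarchical Bayesian estimation of how much subjects value social
images, measured in foregone juice, from aggregated binary choice
counts.

## The problem and the model

In the social-valuation choice paradigm, a monkey chooses between a
juice-only option and a juice-plus-image option whose juice differs by a
differential *dv* (seconds of juice access, `dv = juice_image -
juice_blank`). Indifference occurs when *dv* equals the image value *v*
in magnitude with opposite sign, so *v* is measured in foregone juice
and reported in milliseconds. Data are aggregated counts: per session
*s*, image category *c* (gray-square control, female perinea, dominant
male, subordinate male) and differential, *n* of *N* choices for the
image option.

Per-session logistic fits are fragile (some sessions have only three
distinct *dv* values), and pooling all of a subject's sessions erases
real day-to-day variation. The package's model partially pools:

    v_msc   ~ Normal(V_mc, sigma_m^2)          session values
    eta     = (dv + v_msc) / tau_s             utility
    logit p ~ Normal(eta, omega_m^2)           overdispersed choice
    n       ~ Binomial(p, N)                   counts

with weakly informative priors `V_mc ~ N(0, 0.01 s^2)` (a 100 ms s.d.),
`sigma_m ~ U(1e-6, 1)`, `log omega_m ~ U(-6, 2)`, and a
positively-truncated t prior on the choice-curve width `tau_s` with
uniform hyperpriors on its location, scale, and degrees of freedom. An
optional linear time trend `v_msc ~ N(V_mc + alpha_mc t, sigma_m^2)`
tracks drift of value over a subject's rank-ordered, z-scored session
dates. Eight pooling variants (`modelSpec(0:7)`, from independent
per-session fits to the full hierarchy with trend) are fitted by MCMC
(JAGS via rjags) and compared by DIC; pooling fractions, posterior
predictive checks with logistic choice-curve refits, and subject-level
value/trend/correlation reports complete the pipeline. A forward
simulator generates complete studies with known ground truth.

## Worked example

```r
library(socialval)

# a small two-subject study with known ground truth
design <- studyDesign(c(A = 6, B = 6), dvGrid = c(-0.06, 0, 0.06),
                      nPerBlock = 60)
truth <- realisticTruth(design, seed = 3)
sim <- simulateDataset(truth, design, seed = 4)
sim$dataset
#> ChoiceDataset: 144 blocks | 2 subjects | 12 sessions | 4 categories
#>   dv range [-60, 60] ms; choices per block 60-60

round(1000 * truth@V, 1)   # true mean image values, ms
#>   control female dominant_male subordinate_male
#> A   -28.9    7.8           5.9              2.6
#> B    -8.8  -34.6           0.9             33.5

fit <- runMCMC(modelSpec(6), sim$dataset,
               chainConfig(nChains = 3, nAdapt = 300, nBurn = 800,
                           nIter = 2000, thin = 4, seed = 11))
max(convergenceTable(fit)$rhat)
#> [1] 1.024539

head(valueSummaries(fit), 4)
#>   subject         category     median         lo        hi sdMedian ...
#> 1       A          control -14.726715 -32.832937  2.524188  16.4051
#> 2       A           female  24.160371   6.348489 43.255993  16.4051
#> 3       A    dominant_male   5.969763 -11.339482 23.562415  16.4051
#> 4       A subordinate_male   8.637634 -10.451729 26.364211  16.4051
```

Each row is a subject-by-category posterior: the median image value in
ms of juice access with its central 95% credible interval (subject A's
true values all fall inside; negative values mean the animal must be
paid extra juice to look), plus the posterior for that subject's
across-session value s.d. Diagnostics:

```r
poolingMetrics(fit, sim$dataset)
#> PoolingReport (R^2 = variance explained, lambda = pooling fraction)
#>    level        R2    lambda
#>  session 0.4487235 0.4230819
#>  utility 0.9131540 0.5798948
#>   counts 0.9570241 0.7304391

dic(fit, sim$dataset)
#> DicReport <model6>: Dbar = 745.4, pD = 105.5, DIC = 850.9 (MCSE 0.59)
```

`lambda` is the pooling fraction per model level (1 = complete pooling,
0 = none); DIC is the posterior-mean deviance plus the effective
parameter count, lower is better, used to rank the `modelSpec(0:7)`
variants via `compareModels()`.

A thin command-line front end wraps the pipeline stages
(`inst/scripts/socialval.R simulate|fit|compare|report`); see
`?readRunConfig` for the config keys.

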