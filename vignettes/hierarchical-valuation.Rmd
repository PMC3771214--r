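---
title: "Hierarchical Bayesian valuation of social images from choice counts"
author: "socialval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical Bayesian valuation of social images from choice counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

In the social-valuation ("pay-per-view") paradigm, a monkey repeatedly
chooses between a juice-only option and a juice-plus-image option whose
juice amount differs by `dv` seconds of solenoid-open time. If the animal
values seeing the image, it accepts less juice to see it: the point of
subjective equality (PSE) — the differential at which both options are
chosen equally often — satisfies `dv* = -v`, so the image value `v` is
measured in foregone juice. Values are reported in milliseconds of juice
access; all internal computation uses seconds.

Choice data arrive aggregated: for each session, image category (gray
square control, female perinea, dominant male, subordinate male), and
juice differential, a count `n` of image-option choices out of `N` total.
Sessions are noisy and unequally many per subject, which is exactly the
regime where per-session fits fall apart and complete pooling erases real
day-to-day variation. The package's model partially pools session-level
values toward subject-by-category means, interpolating between those
extremes.

## The model

For monkey `m`, session `s`, category `c`, and a block at differential
`dv`:

* session value: `v_msc ~ Normal(V_mc, sigma_m^2)`
* utility: `eta = (dv + v_msc) / tau_s`
* overdispersed choice probability: `logit p ~ Normal(eta, omega_m^2)`
* counts: `n ~ Binomial(p, N)`

`V_mc` is the mean image value for that subject and category, `sigma_m`
the subject's session-to-session value s.d., `tau_s` a session-specific
utility scale (the choice-curve width; its reciprocal is the logistic
slope), shared in distribution across subjects, and `omega_m` captures
choice variance beyond binomial noise. With a time trend, the session
value model becomes `v_msc ~ Normal(V_mc + alpha_mc * t, sigma_m^2)`,
where `t` is the subject's session date rank-ordered and z-scored.

Priors are weakly informative and identical for every pooling variant:

* `V_mc ~ Normal(0, 0.01 s^2)` — a 100 ms s.d., far wider than observed
  values;
* `sigma_m ~ Uniform(1e-6, 1)` s;
* `log omega_m ~ Uniform(-6, 2)`;
* `tau_s ~ t+(ell, sca, nu)`, a positively-truncated t with
  `ell ~ U(0, 0.5)`, `sca ~ U(1e-4, 0.1)`, `nu ~ U(0.1, 50)` — heavier
  tailed than a truncated normal, reflecting outlier-prone choice-curve
  widths;
* `alpha_mc ~ Normal(0, 0.01)` when the trend is enabled.

## The pooling lattice

`modelSpec(0:7)` spans the comparison lattice: session pooling none
(independent Bayesian per-session fits), complete (one value per group
shared by all its sessions), or partial (the hierarchy above); category
and subject pooling none or complete (collapsing the factor into one
group). The time trend requires partial session pooling. "Complete"
pooling of a factor is encoded by collapsing its index to a single
group; "none" gives independent parameters per level under the same
priors. In the no-session-pooling variant the per-cell values take the
`V` prior directly and there is no `sigma`. The `tau` hyperparameters
are always shared across subjects (no `m` index on `tau_s`).

## Sampling

`runMCMC()` generates a JAGS program for the chosen variant and runs it
through rjags. The posterior is defined by the package's own
`logPrior()`/`logLikelihood()` (the JAGS program is generated from the
same index structure, and the test suite cross-checks the densities by
quadrature and closed forms); JAGS supplies the Markov-chain kernel,
which the contract treats as exchangeable with any correct sampler.
Latent per-block `logit p` (and `v`) are explicit sampled parameters, as
in the hierarchical statement of the model, rather than marginalized.

The reference protocol (`chainConfig()` defaults) is 5 chains, 1000
adaptation iterations, 10,000 burn-in, 20,000 sampling iterations thinned
by 20 — 1000 retained draws per chain, 5000 total. Initialization is
dispersed: group means from the prior, session values at jittered
empirical-logit estimates, utility scales near 50 ms, overdispersion
drawn log-uniformly; per-chain RNG seeds derive from the master seed by a
fixed affine rule, so a seed reproduces every draw bit-for-bit.
Convergence is monitored with split R-hat (threshold 1.1) and an
effective sample size per monitored parameter (`convergenceTable()`).

Numerical choices: `tau` carries a 1e-6 s floor (utilities divide by it);
overdispersion is floored at 1e-8 logit units so the no-overdispersion
limit stays well-defined; the truncated-t prior density is renormalized
over the positive half-line; out-of-support parameter sets get log
density `-Inf` rather than an error. Date ties within a subject take
midranks, and z-scoring uses the population (divide-by-n) s.d., so "unit
variance" is literal for the realized covariate; a single-session
subject gets covariate 0 with a warning.

## The synthetic-data generator

`drawParameters()` draws ground truth from the priors above (truncated-t
draws by rejection, which is exact), or accepts fixed overrides;
`simulateDataset()` then simulates the full generative path and returns
both the dataset and the realized latents for recovery tests. The same
rank/z-score covariate code is used for simulation and fitting, so the
trend enters identically on both sides.

The canonical desk fixture (`canonicalDesign()`) is 4 subjects x 10
sessions x 4 categories x 5 differentials (+/- 80 ms) x 30 choices per
block. `realisticTruth()` fixes parameters at the scale of the reported
behavior — values drawn once from a 30 ms s.d., session s.d. 15-30 ms,
overdispersion 0.2-0.5 logit units, widths 30-70 ms — because draws from
the *full* prior ranges (e.g. `omega` up to `e^2`) produce studies far
noisier than any real session and are useful only for prior-predictive
exercises. `referenceDesign()` reproduces the shape of the motivating
study: 8 subjects with 60, 32, 51, 23, 14, 10, 8, 8 sessions (206
total).

The generator emulates aggregated counts only: it does not model
within-session trial order, block transitions, satiety, or any
reaction-time/eye-position structure. Passing recovery tests therefore
show that the *inference machinery* is calibrated under the model's own
assumptions, not that real macaque behavior satisfies them.

## Diagnostics

**Deviance and DIC.** The deviance focus is the observation level only:
`-2` times the binomial log pmf of the counts given each block's latent
choice probability, excluding all prior terms. `pD` uses the
Spiegelhalter plug-in form `Dbar - D(theta_bar)`, with the posterior
mean of the latent probabilities taken on the logit scale. JAGS's own
penalized-deviance machinery computes its penalty differently, so DIC
values are comparable across variants fitted here but are not bit
targets against other software.

**Pooling fractions.** For each level carrying variance — session values
(`eps = v - (V + alpha t)`, units: session-by-category cells), scaled
utilities (`eps = logit p - eta`, units: blocks), and counts
(`eps = n/N - p`, units: blocks) — the report gives `R^2 = 1 -
var(eps)/var(x)` and the pooling fraction `lambda = 1 -
var(E_u[eps])/var(eps)`. Residuals are taken over posterior draws:
`E_u` is the within-unit posterior expectation and `var(.)` the
population variance pooled over units and draws. A plug-in version
(residuals at posterior means) was considered and rejected: it is
degenerate — group means sit at the center of the shrunken unit
estimates by construction, so `lambda` is forced toward 1 at every level
regardless of how much pooling actually occurred. With draw-based
residuals `lambda` is 1 exactly under complete pooling, 0 under none,
and lies in [0, 1] by the law of total variance.

**Posterior predictive checks.** `posteriorPredictiveSessions()` draws a
retained posterior draw per fictitious session, a width from the
truncated-t layer at that draw's hyperparameters, session values from
the value hierarchy, and counts through the overdispersed binomial.
Observed and fictitious sessions are then refit with the identical
logistic choice-curve code (`logit p = beta0 + beta1 dv`; width
`1/beta1`, PSE `-beta0/beta1`) and compared by two-sample KS tests on
the fitted value and width distributions. Complete separation is
flagged and the diverging fit reported as-is, never replaced by a
fabricated value; flagged fits are excluded from the KS comparison on
both sides.

**Shrinkage check.** "Partial pooling interpolates between no pooling
and complete pooling" is operationalized as: the posterior mean of each
session value lies between the session's no-pooling estimate and the
fitted subject-by-category mean, within one standard error of the
no-pooling estimate. The no-pooling estimate inverts the empirical logit
(half-count continuity correction) at the posterior-mean utility scale.
The tolerance is there because the no-pooling estimator itself carries
~10 ms of sampling noise on the canonical fixture; demanding strict
betweenness of three noisy point estimates fails for a quarter of cells
even though the overshoot is a small fraction of the posterior s.d.

## Reporting conventions

Summaries use type-7 (R default) quantile interpolation, pinned by test:
sorted draws 1..1000 give the central 95% interval (25.975, 975.025).
All reported millisecond quantities are exactly 1000 times the
second-scale posterior quantiles; negative values are reported as-is.
Trend slopes are reported on the fitting scale (ms per
standardized-rank unit) alongside an approximate per-session rescaling
(dividing by the population s.d. of the subject's session ranks), since
the two differ by a subject-dependent factor. Cross-category scatter
samples select whole (session, draw) pairs uniformly with replacement —
never mixing categories across draws — so within-draw correlation
structure survives; the test suite verifies that independent per-column
shuffling destroys it.

## Desk-scale experiment sizes

The packaged experiments are sized for a single workstation: recovery
uses 20 replications of the canonical fixture with 3 chains x (300
adapt, 600 burn, 1600 iterations thinned by 8); the convergence
demonstration uses a 2-subject, 100-choices-per-block design with 3
chains x (1000, 4000, 12,000/12), which reaches split R-hat < 1.1 on
every monitored parameter; model-comparison experiments use 3-subject
designs. These short chains are adequate for group-mean recovery;
utility-scale and overdispersion parameters mix slowly (they trade off
along a ridge in `eta = (dv + v)/tau`), which is why the reference
protocol runs 20,000 iterations and why convergence should always be
checked via `convergenceTable()` before reporting.

## Known limitations

* Reproducing the archived study's numeric tables requires the archived
  dataset and full-length chains; the package treats those values as
  comparability targets (same machinery, same definitions) rather than
  bit targets, the `pD` definition being the main comparability caveat.
* The per-subject z-scoring of session dates is an interpretation (the
  covariate feeds a per-subject regression); `sessionTimeCovariate()` is
  the single switch point if a pooled ranking is ever wanted.
* Whether the non-hierarchical comparison fits used the same prior
  ranges is unknowable from the source; the same `PriorConfig` defaults
  are used for all variants.
* The exploratory cross-category scatter sampling is deliberately not a
  Bayesian estimate of a correlation matrix.
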