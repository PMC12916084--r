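---
title: "Methods: biphasic growth, longevity and the temperature-size rule"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biphasic growth, longevity and the temperature-size rule}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

The temperature-size rule predicts that ectotherms in warmer environments
grow faster as juveniles, mature earlier, and mature at smaller sizes; for
indeterminate growers like fish this is often extrapolated to smaller
maximum sizes.  Testing all of those predictions at once in wild
populations requires estimating *stage-specific* growth — not just average
body size — across a thermal gradient.  `tsrgrowth` implements that full
chain for standard agency lake surveys: thermal covariates, age-length-key
expansion, a hierarchical biphasic growth model, a longevity regression,
and derived size posteriors.

## The biphasic growth model

Length at age is piecewise linear and continuous at the change point:

$$\mu(a) = \alpha + \beta_1 \min(a, A_{mat}) + \beta_2 \max(a - A_{mat}, 0),$$

where $\alpha$ (cm) is length at age 0, $\beta_1$ (cm/yr) the juvenile
growth rate, $A_{mat}$ (yr) the change point — a proxy for age at
maturity, where energy is redirected from somatic growth to reproduction —
and $\beta_2$ (cm/yr) the adult growth rate.  Observed lengths are
lognormal about $\mu$:
$y_i \sim \mathrm{LN}(\log \mu_i, \sigma_j)$ with a per-species scale
$\sigma_j$.  We parameterise the lognormal by its *median* ($\mu$ is the
expected length on the natural scale in the field's usual reading); the
mean-parameterised alternative differs by the factor
$\exp(\sigma_j^2/2) \approx 1.01$ at the default $\sigma_j \approx 0.13$
and would not change any qualitative conclusion.

Survey-level parameters (one set per species $\times$ lake $\times$ year)
are drawn from normals around linear predictors in the scaled thermal
covariate $T$:

$$\phi_{p} = \gamma_{0p}(j) + (\gamma_{1p} + \tau_{jp})\,T + \omega_{lp},
  \qquad p \in \{\beta_1, A_{mat}, \beta_2\},$$

with $\phi_\alpha = \gamma_{0\alpha}(j) + \omega_{l\alpha}$ (the age-0
intercept is hard to interpret as a function of temperature and carries
only a lake effect).  $\gamma_{0p}$ are species baselines
(Uniform(0, 30) priors), $\gamma_{1p}$ global temperature slopes
(Normal(0, 1) priors), $\tau_{jp}$ species random slopes and
$\omega_{lp}$ lake random intercepts (centred normals).  All
variance-scale hyperparameters — process SDs $\sigma_{\phi.p}$,
random-effect SDs $\sigma_{\tau.p}$, $\sigma_{\omega.p}$ and observation
scales $\sigma_j$ — carry Gamma(1, 1) priors.  A "Gamma prior on
$\sigma^2$ parameters" is ambiguous between the variance, its SD and its
reciprocal; in Gibbs-sampler practice the idiom is a Gamma prior on the
*precision* $1/\sigma^2$, which is also conditionally conjugate, so that
placement is the default (`var_prior = "precision"`).  The
SD placement (`var_prior = "sd"`) is available; it concentrates more
prior mass at small scales and, being non-conjugate, mixes noticeably
more slowly through the variance components.

Survey-level parameters are truncated to their biological supports:
$\alpha \ge 0$, $\beta_1 > 0$, $A_{mat} \in [0.25, 30]$ yr, $\beta_2$
unconstrained (adult growth is empirically positive here but nothing in
the biology forbids shrinkage).  Predicted means are floored at $10^{-6}$
cm before logs so the likelihood is defined everywhere the sampler can
reach.

## Thermal covariates

Annual growing degree days above 5 °C (GDD5) is the cumulative sum of
daily degrees above the base — a standard index of the thermal energy a
lake receives.  The modelling covariate is the mean GDD5 over the ten
years up to and including the survey year, capturing the regime
experienced by the younger age classes that dominate the samples; window
means over 5 vs. 10 years are nearly collinear across a lake gradient, so
the window choice is not critical.  The covariate is z-scored across all
modelled lake-years (`scale_covariate()` keeps the centre/scale record
for back-transformation): slopes of order 0.1–1 under Normal(0, 1) priors
are only sensible on a standardised axis, not per raw degree-day.
Missing-day tolerance defaults to zero (synthetic
series are complete); `compute_window_mean()` has a strict policy that
errors on incomplete windows with an `"available"` fallback.

## Age-length keys and the survey filter

Only a length-stratified subsample of measured fish is laboratory-aged in
agency practice.  For each survey passing the inclusion filter — at least
5 distinct age groups with at least 5 aged fish each, read as "at least
five *qualifying* groups" so that one stray old fish never disqualifies a
survey — a 1-cm age-length key is built from the aged subsample and the
remaining fish draw a seeded stochastic age from their length bin.
Stochastic (rather than modal) assignment preserves the age-composition
variance that the growth likelihood assumes.  Fish outside the key's
length range are dropped with a logged count by default
(`policy = "nearest"` reassigns them instead).  Bin width, assignment
rule and out-of-range policy are all config-exposed — agency protocols
vary and no single convention is canonical.

## Sampling and diagnostics

The posterior is sampled with JAGS (Gibbs/slice sampling) from a model
specification generated by the package; the exact target density is also
implemented natively (`growth_logprior()`, `growth_loglik()`,
`growth_logposterior()`) and the two are held together by oracle tests.
Two implementation choices matter for mixing:

* the species-slope hierarchy is sampled in *hierarchically centred* form
  ($\eta_{jp} \sim N(\gamma_{1p}, \sigma_{\tau.p})$, with
  $\tau_{jp} = \eta_{jp} - \gamma_{1p}$ recovered deterministically) —
  identical joint distribution, far shorter autocorrelation times for
  $\gamma_1$ under one-at-a-time updates;
* chains are initialised from a per-species least-squares biphasic
  profile fit (`fit_biphasic_ls()`), which removes most burn-in
  transients.

The desk-scale default is 3 chains of 10,000 iterations, burn-in 2,000,
thinning 4 (2,000 retained per chain).  The burn-in and retained draw
count follow the desk-scale convention; total iterations are set so that
*every* monitored parameter — including the slowest-mixing variance
components — clears an effective sample size of 300 within the run.
`full_mcmc_config()` provides the full-scale configuration (3 × 125,000,
burn-in 30,000, thinning 10) for cluster-length runs on million-record
datasets.  The longevity regression keeps the same desk default: a
heavily thinned long run (say 3 × 50,000 with burn-in 40,000 and
thinning 100) retains only 300 pooled draws, too few for the ESS bound
it is checked against, so the desk default's 2,000 retained draws per
chain are the sensible operating point.

Convergence is assessed with rank-normalised split R-hat and
autocorrelation effective sample size (Geyer initial monotone positive
sequence), at the conventional thresholds R-hat < 1.1 and ESS > 300.
These are the modern formulations of the classic diagnostics; the
thresholds, not the formulas, carry the semantics.  A constant chain
reports ESS 0 and R-hat `NA`.  Significance of an effect is declared when
its 95% highest-posterior-density interval excludes zero.

## Longevity and derived sizes

Longevity is proxied by the 95th percentile of observed ages per
population (`compute_a95()`, linear order-statistic interpolation; the
common default, config-switchable), computed on the age-length-key
expanded sample — "fish in each population", not just the aged subsample.
It is regressed on the same scaled covariate with species offsets,
species × temperature interactions and lake random intercepts, Gaussian
errors, Normal(0, 10) coefficient priors and half-Normal(0, 10) SD priors
(a literal Normal(0, 10) cannot apply to a positive SD).

Size at maturity per posterior draw is
$L_{mat} = \alpha + \beta_1(T)\,A_{mat}(T)$, inheriting every source of
uncertainty.  Lifetime curves and maximum size combine the *independent*
growth and longevity posteriors: draws are paired by seeded random
subsampling to the common draw count — random pairing preserves both
marginals and assumes posterior independence, which holds by
construction when the two models are fitted separately.  A paired draw
with $A_{max} < A_{mat}$ is floored to $A_{mat}$ — the curve ends at
maturity — and the floored fraction is reported.  Curves are evaluated on
a 0.1-yr age grid up to the 97.5% posterior quantile of $A_{max}$, and
the three standard regimes sit at the 5th/50th/95th percentiles of the
observed covariate.

## The synthetic generator

`simulation_config()` + `simulate_dataset()` emulate the structure the
analysis assumes: lakes along a 1500–3000 degree-day climate gradient
(sinusoidal annual temperature cycle, lake offsets solved numerically to
hit target GDD5, Gaussian day noise); species baselines drawn from a pool
of seven upper-Midwest life histories spanning slow panfish to fast
esocids; survey-level truths generated by the hierarchy itself
(truncated normals around the linear predictors); ages from a truncated
geometric distribution over 0..$A_{max}$ (survival 0.75/yr, so young
fish dominate and age-0 young-of-year appear, as in fall surveys);
lognormal lengths; and a per-bin aging quota of 5 fish per 1-cm bin.
Default effects ($\gamma_1$ = +0.5, −0.5, 0 for juvenile growth, age at
maturity and adult growth; −0.4 yr/SD for longevity) encode a
temperature-size-rule world at magnitudes comparable to those reported
for wild populations.

What the generator does *not* emulate — gear selectivity, sexual size
dimorphism, aging error by structure, depth-resolved thermal refugia,
lake productivity gradients — bounds what passing tests show: parameter
recovery demonstrates the *inference machinery* is correct under the
model's own assumptions, not that the model is adequate for any given
real survey programme.

## Problem sizes and numerical choices

Testing uses three scales, chosen as sensible desk-scale designs: a
recovery design of 2 species × 40 lakes × 2 years × 60 fish (~9,600
fish) for sign and magnitude recovery of all three temperature effects; a
20-replicate coverage design of 1 species × 20 lakes × 40 fish with a
shortened chain (4,000 iterations, 500 retained per chain) whose 95%
interval for the juvenile-growth effect is checked against the exact
binomial band around nominal coverage; and a 40-lake × 3-species
longevity design (240 records).  Degenerate inputs are handled
explicitly: zero-variance covariates refuse to scale, empty surveys
refuse key construction, single chains refuse R-hat/ESS, constant chains
report ESS 0, and all truncation/flooring rules above are exact rather
than silent clamps of data.

## Known limitations

* The change point is only a proxy for maturity; strongly dome-shaped or
  asymptotic growth will bias $\beta_2$ upward near the break.
* With few species the global slopes $\gamma_{1p}$ and species slopes
  $\tau_{jp}$ separate only through the prior; species-specific *totals*
  ($\gamma_{1p} + \tau_{jp}$) are the robustly identified effects.
* The 95th-percentile age conflates mortality and sampling; it is a
  longevity proxy, not a survival estimate.
* Growth and longevity posteriors are combined as independent; in a
  joint model they would correlate through shared lake effects.
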