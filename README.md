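# tsrgrowth

Testing the temperature-size rule in wild freshwater fish from standard
agency age-length surveys.

The temperature-size rule predicts that ectotherms in warmer waters grow
faster as juveniles, mature earlier, and mature — and perhaps top out — at
smaller sizes. Deciding whether wild fish actually do this requires
estimating stage-specific growth, not just average body size, across a
thermal gradient. `tsrgrowth` implements the full analytical chain:

* **Thermal covariates** — annual growing degree days above 5 °C (GDD5)
  per lake-year and the trailing 10-year mean
  $\bar T_{10}$, z-scored for modelling.
* **Age-length keys** — per-survey length-bin × age probability tables
  built from the aged subsample, a 5-age-groups × 5-fish survey inclusion
  filter, and seeded stochastic age assignment for length-only fish.
* **The core model** — a hierarchical Bayesian biphasic (hockey-stick)
  growth model: length at age
  $\mu(a) = \alpha + \beta_1 \min(a, A_{mat}) + \beta_2 \max(a - A_{mat}, 0)$
  with lognormal observation error; survey-level parameters vary around
  species baselines $\gamma_{0p}$ with global temperature slopes
  $\gamma_{1p}$, species random slopes $\tau_{jp}$ and lake random
  intercepts $\omega_{lp}$; Uniform(0,30), Normal(0,1) and Gamma(1,1)
  priors; MCMC via JAGS with the exact target density also implemented
  natively and oracle-tested.
* **Longevity** — a Bayesian Gaussian regression of the 95th-percentile
  age per population on temperature with species interactions and lake
  random intercepts.
* **Derived sizes** — posterior size at maturity
  $L_{mat} = \alpha + \beta_1(T) A_{mat}(T)$, lifetime growth curves and
  maximum size $L_{max}$ under cool/median/warm regimes, propagating all
  posterior uncertainty.
* **Diagnostics** — rank-normalised split $\hat R$, autocorrelation
  effective sample size, and 95% HPD significance, implemented from first
  principles.
* **A synthetic survey generator** with known truths (lakes on a climate
  gradient, species with contrasting life histories, length-stratified
  aging quotas), so every stage is testable end to end.

## Worked example

The numbered drivers under `analysis/` run the whole study on the
synthetic dataset (40 lakes × 2 species × 2 years, 60 fish/survey,
generating effects $\gamma_{1\beta_1} = +0.5$, $\gamma_{1A_{mat}} = -0.5$,
$\gamma_{1\beta_2} = 0$):

```sh
Rscript analysis/01_simulate.R        # ~seconds
Rscript analysis/02_thermal.R
Rscript analysis/03_age_assignment.R
Rscript analysis/04_fit_growth.R      # ~10 min (add --full-mcmc for the full run)
Rscript analysis/05_fit_longevity.R
Rscript analysis/06_derived_sizes.R
Rscript analysis/07_report.R
```

The early stages print, for example:

```
simulated 9600 fish across 160 surveys (40 lakes x 2 species x 2 years)
aged subsample after the per-bin quota: 8086 fish (84%)
annual GDD5 spans 1454-3044 degree-days across 40 lakes
10-year mean covariate: 2260 +/- 448 degree-days (z-scored for modelling)
102 of 160 surveys pass the 5x5 filter
```

The growth fit (stage 4) reports convergence and the recovered
temperature effects (posterior mean and 95% HPD, per SD of the thermal
covariate):

```
fitted 6120 fish in 102 surveys; max r-hat 1.002, min ESS 644
gamma1_beta1 = 0.40 [-0.81, 1.57]
gamma1_amat = -0.37 [-1.51, 0.81]
gamma1_beta2 = -0.01 [-1.18, 1.13]
```

and stage 7's effect table resolves the species-specific totals
($\gamma_{1p} + \tau_{jp}$ — with only two species the *marginal* slope
is wide while the species totals are sharply identified):

```
  gamma1_beta1   bluegill       +0.63 [+0.45, +0.81] *
  gamma1_beta1   northern_pike  +0.54 [+0.35, +0.74] *
  gamma1_amat    bluegill       -0.57 [-0.80, -0.34] *
  gamma1_amat    northern_pike  -0.52 [-0.74, -0.29] *
  gamma1_beta2   bluegill       +0.04 [-0.15, +0.22]
  gamma1_beta2   northern_pike  -0.08 [-0.35, +0.19]
```

Juvenile growth rises and age at maturity falls in warm lakes while
adult growth is flat — matching the generating truths of +0.5, −0.5 and
0 (`*` marks HPD intervals excluding zero). Stage 6 prints size at
maturity, maximum size and maximum age per species and temperature
regime, e.g. northern pike maturing at 53.6 cm in the coolest lakes
versus 42.6 cm in the warmest, and stage 7 writes the effect table and
growth-curve figures.

Equivalently in R, `run_pipeline(pipeline_config(...), outdir)` executes
the same stages with CSV artifacts and a byte-reproducible JSON manifest.

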