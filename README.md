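# seqbenefit

Who should get the organ?  When a scarce, single-shot treatment (the
motivating example is a donor liver) becomes available at some calendar
date, a sickest-first rule gives it to the patient with the worst
short-term waiting-list prognosis.  `seqbenefit` instead estimates, for
every eligible patient on the list and for the *specific offer at hand*,
the **conditional survival benefit**: the expected life-years gained
over a fixed horizon L if this patient is treated now rather than never,

```
d_l(Sk | Zk)  =  RMST1,l(Sk | Zk)  -  RMST0(Sk | Zk),
```

the difference between two restricted mean survival times on the reset
clock `u = t - Sk`, where `Sk` is the patient's waiting time at the
decision date and `l` indexes the offer (its quality covariates `Z*`).

Estimation emulates a sequence of target trials on calendar
cross-sections.  At each date the eligible patients are followed under
the strategies "never treat" (artificially censored at deviation, i.e.
at treatment) and "treat now with this offer".  Stabilized
inverse-probability-of-treatment weights — a time-varying Cox-model
ratio for the never-treated arm, a complementary log-log receipt model
for the treated arm — undo the time-dependent confounding created by a
covariate (think MELD) that drives both treatment assignment and
mortality.  Weighted marginal structural Cox models per arm
(`lambda_a(u|x) = lambda_0a(u) exp(beta_a' x)`, Breslow baselines and
ties) then yield the two survival curves, their restricted means, and
the benefit, for ranking patients at any decision date.

The package is aimed at biostatisticians working on allocation policy:
it contains the full estimation pipeline for registry-style long-format
data, the longitudinal data-generating mechanism of the accompanying
simulation study (Ornstein-Uhlenbeck covariate; treatment, mortality and
post-treatment hazards driven by it), exact ground-truth oracles, two
comparator estimators (a naive baseline-covariate analysis and the same
cross-section pipeline without weights), and a calibration-based
evaluation harness.

## Worked example

Simulate a 1,000-patient waiting list over a 10-year window, fit the
weighted sequential MSM, and rank the patients standing on the list at
one decision date against one offer:

```r
library(seqbenefit)

cfg <- dgm_config(n_patients = 1000, seed = 42)
pop <- generate_population(cfg)
pop
#> <sb_population> 1000 patients: 294 died untreated, 389 treated,
#>   317 administratively censored

ds  <- cross_section_dates(cfg)
res <- fit_benefit_msm(pop$episodes, pop$measurements, pop$offers,
                       ds$coarse, ds$fine)
weight_diagnostics(res$wstack)
#> stabilized weights: mean 0.9756 (max 14.73) before capping; mean 0.9756
#> (max 14.73) after capping at the 1.0000 quantile (0 intervals capped,
#> 13 treated rows outside positivity)

round(res$fit$arm0$coef, 3)   # never-treated arm:  Z 1.486, wait 0.404
round(res$fit$arm1$coef, 3)   # treated arm:        Z -1.637, Zstar 1.199
```

The never-treated coefficient on `Z` (1.486, robust SE 0.108) says a
one-unit worse covariate multiplies waiting-list mortality by ~4.4; the
treated-arm coefficients say sicker-at-treatment patients die faster
after treatment than their covariate alone would suggest
(`Z` -1.637 picks up the *reversed* marginal relation induced by the
nonlinear simulated effect) and a one-unit worse offer multiplies
post-treatment mortality by ~3.3.

Ranking the 140 patients eligible at calendar date 4.48 against an
offer of quality `Z* = -0.5`:

```r
snap <- res$stacks$never[k == 113]
predict_benefit(res$fit, snap, offer = list(Zstar = -0.5))
#>    patient_id   Sk rmst0_hat rmst1_hat benefit_hat rank
#> 1:        724 0.75      0.52      2.98        2.46    1
#> 2:        789 0.58      0.57      2.98        2.41    2
#> 3:        451 0.17      0.63      2.98        2.34    3
#> 4:        746 0.38      0.67      2.98        2.31    4
#> 5:        494 0.32      0.75      2.97        2.23    5
#> ...
```

Patient 724 is expected to live 0.52 of the next 3 years without this
transplant and 2.98 with it — a benefit of 2.46 life-years, the top
claim on this offer under benefit-based allocation.

The evaluation harness replicates the whole study and reports smoothed
calibration (estimated vs. true restricted means) per method:

```r
study <- run_replications(dgm_config(n_patients = 500), n_runs = 20,
                          seed = 1)
study$summary            # rms calibration bias per method x estimand
plot_calibration(study)  # 3 x 3 curve panel (needs ggplot2)
```

A thin command-line front end over the same functions is installed at
`inst/cli/seqbenefit.R` (subcommands `simulate`, `fit`, `predict`,
`evaluate`).

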