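---
title: "Estimating conditional survival benefit with sequential cross-section MSMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating conditional survival benefit with sequential cross-section MSMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqbenefit)
library(data.table)
```

## The question the package answers

On a waiting list for a scarce, single-shot treatment — the motivating
case is liver transplantation — an offer arrives at a calendar date and
must go to one of the patients currently on the list.  A sickest-first
rule ranks patients by short-term waiting-list mortality (e.g. the MELD
score).  An alternative is to rank by *benefit*: the expected life-years
gained, over a fixed horizon $L$, if the offer is delivered to this
patient now rather than never.  `seqbenefit` estimates, for every patient
$i$ eligible at a decision date and for the specific offer $\ell$
available then,

$$d_\ell(S_k \mid \bar Z_k) \;=\; \mathrm{RMST}_{1,\ell}(S_k \mid \bar Z_k)
  \;-\; \mathrm{RMST}_0(S_k \mid \bar Z_k),$$

where $S_k$ is the patient's waiting time at cross-section date $CS_k$,
$\bar Z_k$ the covariate history up to that date, and the two terms are
restricted mean survival times over $(0, L]$ under the strategies "treat
now with offer $\ell$" and "never treat".  Both are areas under
counterfactual survival curves on the reset clock $u = t - S_k$.

## The estimator

Each date at which a treatment unit becomes available defines a
cross-section: a new time origin for the patients alive, untreated,
uncensored, and eligible just before that date.  Stacking these
cross-sections emulates a sequence of target trials.  Within each one:

* the **never-treated arm** follows every eligible patient from $u = 0$,
  artificially censoring them the moment they deviate from the strategy,
  i.e. when they receive treatment;
* the **treated arm** contains, at each fine-grid date, the patient who
  actually received that date's offer, followed from treatment on the
  residual clock.

Artificial censoring is informative whenever time-varying covariates
drive both treatment assignment and mortality, so each arm is reweighted
by stabilized inverse-probability-of-treatment weights:

* never-treated intervals get
  $W_k(u) = \exp\{\int_{S_k}^{S_k+u}\hat\lambda^{den}_0(t\mid Z(t))\,dt -
  \int_0^u \hat\lambda^{num}_{0,k}(u'\mid Z_k)\,du'\}$, a ratio of the
  predicted probabilities of remaining untreated under a numerator model
  with covariates frozen at the cross-section (one Breslow baseline per
  cross-section, shared coefficients) and a denominator Cox model with
  time-varying covariates on the original time scale;
* treated rows get $\hat\lambda_{1,num} / \hat P(\text{treated at }k
  \mid Z_k, Z^*)$, the pooled empirical treatment rate over a
  complementary log-log model for receipt of the specific offer given
  patient and offer covariates.

Weighted Cox models (Breslow ties and baselines throughout) then give
the two marginal structural hazards
$\lambda_{a}(u \mid \cdot) = \lambda_{0,a}(u)\exp(\beta_a^\top x)$,
$a \in \{0, 1\}$, whose survival curves are integrated to the two RMSTs
and the benefit.  `fit_msm()` fits the arms separately by default; the
`joint` mode reproduces the same estimates inside one partial likelihood
with arm-stratified baselines, which is convenient when a single model
object is preferred.

The causal reading requires the usual conditions — consistency,
positivity, and conditional exchangeability given the covariate history
at each cross-section — plus conditionally independent censoring; the
package assumes all of these and does not attempt censoring reweighting.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `horizon_L` | 3 y | RMST horizon; all follow-up truncates here |
| `cs_spacing_coarse` | 0.04 y | date grid for the never-treated arm (many untreated patients per date make a fine grid unnecessary) |
| `cs_spacing_fine` | 0.01 y | date grid for the treated arm (captures nearly every treatment) |
| `weight_dt` | 0.04 y | resolution at which time-varying weights update |
| `cap_quantile` | 1 (simulation), 0.9999 (application-style) | weight truncation quantile |
| `intercept_mode` | `"pooled"` | cloglog intercept shared across cross-sections, or a calendar natural spline |
| `baseline_policy` | `"pooled"` | one Breslow baseline per arm; per-calendar-period strata and a log-linear calendar trend are available for prediction at future dates |

The weight resolution deserves a note: weights are step functions whose
jumps come from Breslow baselines, so the cumulative hazards entering
each interval's weight are evaluated *exactly* at the interval
endpoints; `weight_dt` only controls how long a weight is held constant.
At the simulated event rates, refining `weight_dt` from 0.04 to 0.01
changes weights by well under 0.1% while quadrupling the size of the
weighted dataset, so the coarse cross-section spacing is used.

## The simulated world

`generate_population()` draws, per patient: an entry date uniform on the
observation window; one time-varying covariate
$Z(t) = \mu + \eta t + \xi(t)$ with $\mu \sim N(0,1)$, $\eta \sim
N(0, 0.5)$ and $\xi$ a mean-zero Ornstein–Uhlenbeck process
($\theta = 0.1$, $\sigma = 0.0045$, started from the 100th burn-in
update of 0); a never-treated death time with hazard $0.2t\,e^{1.5 Z(t)}$;
a latent treatment time with hazard $0.25t\,e^{2 Z(t)}$; and, for
patients observed treated, an offer quality $Z^* \sim N(0,1)$ and a
post-treatment residual death time with hazard
$0.075v\,e^{f(Z(T)) + Z^*}$.  The effect $f$ is piecewise linear — flat
at $1.2$ below $-0.6$, slope $-2$ between $-0.6$ and $0.6$, flat at
$-1.2$ above — so every estimation model (all assume linearity) is
deliberately misspecified.  Patients enter a cross-section only while
$Z > -1$, which emulates removal from the list upon improvement and
keeps the waiting-list covariate distribution roughly stable.

What the generator does *not* emulate: informative (non-administrative)
censoring, multiple patient covariates, measurement error, or sparse
irregular covariate sampling — the simulated $Z$ is observed on a dense
0.01-year grid.  Passing tests therefore demonstrate internal validity
of the estimator under continuous monitoring with a single confounder,
not robustness to the messiness of registry data.

Ground truth for evaluation is the *individual* RMST given the latent
covariate path: $\mathrm{RMST}_0 = \int_0^L \exp\{-\int_{S_k}^{S_k+u}
h_0(s \mid Z(s))\,ds\}\,du$, with the inner integral accumulated exactly
per grid cell, and the closed-form
$\mathrm{RMST}_1 = \tfrac12\sqrt{\pi/a}\,\mathrm{erf}(\sqrt a L)$ with
$a = \tfrac{0.075}{2} e^{f(Z_k) + Z^*}$.  Marginalization over future
covariate paths happens implicitly through the calibration smoother.

## Numerical choices

* **OU simulation** uses the exact Gaussian transition, not
  Euler–Maruyama, so the path law is correct at any step size; burn-in
  steps reuse the grid step.
* **Event times** are drawn by inverse-transform sampling with the
  linear baseline integrated in closed form within each grid cell and
  the covariate held at the cell's left value.  The truth oracle uses
  the *same* left-endpoint convention deliberately: the oracle must
  describe the law the data were actually drawn from.  Halving the grid
  step moves individual truth values by up to about $10^{-3}$ years.
* **Ties** use the Breslow approximation everywhere, matching the
  Breslow baselines that the weight integrals and survival predictions
  are built from.
* **Weight evaluation** at interval right endpoints (the
  counting-process convention); capping, when enabled, applies to the
  pooled weight distribution of both arms.
* **Vectorized RMST prediction** samples each survival step function at
  0.01-year cell midpoints, accurate to about $10^{-4}$ years; the
  user-facing `rmst_from_survival()` integrates step functions exactly.
* **Degenerate inputs**: cross-section rows with zero residual
  follow-up are dropped and counted; strata without treatment events get
  flat numerator baselines and a message; separation in the cloglog
  model falls back to a ridge-stabilized fit with a warning.

## Design decisions in ambiguous territory

**Eligibility is an inclusion rule, not a hazard gate.**  The $Z > -1$
rule decides who stands in a cross-section's risk set.  The latent
treatment process is not gated by it, so a few percent of simulated
recipients are formally ineligible at their own treatment date.  Three
consequences, chosen deliberately and consistently: recipients always
enter the treated *stack* (a delivered treatment is evidence enough of
being on the list; excluding them would make the cross-section treated
arm systematically unlike the naive comparator's, contradicting the
expectation that the two estimate post-treatment survival from nearly
the same patients); the *weighted* pseudo-population drops those
recipients, because under an eligibility-gated treatment hazard their
receipt probability is zero and no inverse-probability weight exists
(`n_positivity_dropped` in the diagnostics); and the weight-model fits
do not remove ineligible person-time from risk sets by default
(`gate_eligibility = TRUE` restores strict gating for applications where
treatment genuinely cannot reach ineligible patients — gating on this
simulated mechanism biases the null-confounding denominator coefficient
and drags mean weights visibly below 1, since it deletes real events
selected on $Z$).

**The stabilization covariates.**  The numerator model uses the same
frozen covariates as the outcome model: the patient covariate and the
waiting time.  Weight diagnostics motivated including waiting time: the
simulated treatment intensity grows linearly in follow-up time, so
patients with long waits are treated (hence artificially censored)
faster, and a numerator blind to waiting time lets the mean stabilized
weight drift far below one at late $u$ through informative depletion.
With waiting time included the drift shrinks to the percent level
(the suite tests centering within 5% per decile of the reset clock).
It cannot be removed
entirely within this model family: under a linearly growing treatment
intensity the true probability of remaining untreated is *additive* in
(waiting time, $u$) on the cumulative-hazard scale, which no
frozen-covariate proportional-hazards numerator represents exactly.
This is a known structural limit, visible in the weight diagnostics.

**The naive comparator's predictions.**  Its never-treated Cox model
(time origin at first eligibility, baseline covariate $Z(0)$) predicts
residual survival at waiting time $S_k$ as the conditional survival
$S(S_k + u \mid z)/S(S_k \mid z)$ with the patient's *current* covariate
value plugged in as $z$; its post-treatment model is censored at the
horizon so that, when every treatment time lies on the fine grid, it
coincides with the cross-section treated-arm model exactly.  The
post-treatment model includes the offer covariates — without them the
comparator could not produce offer-specific RMSTs at all.

**Evaluation smoother.**  Calibration pools every (patient,
cross-section, replication) triple; the smoothed curve is a local-linear
loess (span 0.75) of truth on estimate, fitted on a deterministic
thinning of at most 20,000 points in estimate order and evaluated
everywhere by interpolation on a 401-point grid; the root mean squared
bias summarizes the curve-to-diagonal distance over points inside the
1st–99th percentiles of the estimates, which keeps smoother boundary
artifacts out of the summary.  Truth for the treated estimand at a
non-treatment date scores every eligible patient against that date's
drawn offer.

**Randomness.**  Each run consumes a single seeded stream in a fixed
draw order, which makes populations bit-identical across repeats;
replication $r$ of an evaluation study uses `seed + r - 1`.

## Problem sizes

The replicated evaluation in the test suite runs 50 replications of
1,000 patients (the full study design is 200 × 2,500); the
parameter-recovery check runs one population of 2,500 under the
linear-effect variant; the weight-contract checks run one population of
1,000 with treatment independent of the covariate.  The acceptance
script uses the 20 × 500 smoke scale.  These sizes were chosen so the
whole suite completes comfortably on a single CPU while leaving the
qualitative ordering of the methods and the parameter-recovery bands
stable across seeds.

## Known limitations

* The marginal never-treated hazard is genuinely non-proportional under
  the simulated covariate dynamics, so the fitted coefficient on $Z_k$
  attenuates relative to the conditional effect: the marginal
  structural model marginalizes over future covariate drift, and
  survival selection erodes the hazard ratio as $u$ grows.  This is a
  property of the estimand, not an estimation error, and it is why the
  calibration evaluation — not coefficient recovery — is the primary
  performance measure.
* Absent confounding the three estimators still differ: the naive model
  ignores covariate drift after its baseline (a model-form gap
  unrelated to confounding), and the treated-arm receipt weights vary
  with waiting time by construction (receipt probability grows with
  follow-up time), so under a misspecified outcome model weighting
  shifts the fitted linear approximation and adds variance.  Exact
  three-way equivalence under a treatment-independent-of-covariate
  mechanism therefore holds only for the weighted-versus-unweighted
  never-treated comparison.
* Only the strategies "never treat" and "treat now with this offer" are
  implemented; "treat later" strategies are out of scope.
* No inverse-probability-of-censoring weights: censoring is assumed
  conditionally independent given the cross-section covariates.
* Benefit is estimated as a difference of two RMST estimates, not as a
  single direct estimand; no confidence intervals are reported for it
  (robust standard errors are reported for the model coefficients).
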