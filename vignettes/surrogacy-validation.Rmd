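---
title: "Validating surrogate endpoints for overall survival: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating surrogate endpoints for overall survival: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surroval)
library(ggplot2)
```

## The problem

Overall survival (OS) is the gold-standard endpoint of chemotherapy and
radiotherapy trials in lung cancer, but it takes many years to read out.
Earlier endpoints — disease-free survival (DFS) after surgery,
progression-free survival (PFS) in locally advanced disease, and
locoregional control — are candidates to replace it, *if* they can be
shown to be valid surrogates. The accepted standard of evidence is a
two-level analysis of individual patients' data pooled across randomised
trials:

* **Individual level** — within patients, how strongly are the surrogate
  time and the survival time associated? This is summarised by the
  squared rank correlation $\rho^2$, estimated under censoring.
* **Trial level** — across trials, how well does the treatment effect on
  the surrogate (log hazard ratio, $\log \mathrm{HR}_S$) predict the
  treatment effect on OS ($\log \mathrm{HR}_T$)? This is summarised by
  the $R^2$ of a linear regression weighted by trial size, together with
  the *surrogate threshold effect* (STE) and a leave-one-trial-out
  (LOO) check of the prediction intervals.

A surrogate is convincing only when both coefficients are close to 1.
`surroval` implements the whole pipeline — endpoint derivation from raw
event histories, Kaplan-Meier and per-trial Cox estimation, the censored
copula model, the weighted trial-level regression, STE, fixed-horizon
sensitivity analyses and LOO validation — plus a synthetic multi-trial
generator with *known* association at both levels, so every stage can be
tested without access to patient records.

## Endpoint definitions

From each patient's event history (times of locoregional events, distant
events, death, and last follow-up) the package derives:

* **OS** — time to death from any cause; censored at last follow-up.
* **DFS / PFS** — time to the first of locoregional event, distant event
  or death; censored at last follow-up. The two names label the same
  composite in the operable and locally advanced settings.
* **Locoregional control** — time to the first locoregional event;
  patients with distant progression, who died, or without a documented
  locoregional event are censored at the date of distant progression,
  death or last follow-up, whichever comes first. This is deliberately a
  censoring treatment, not a competing-risks cumulative incidence, to
  match how such meta-analyses are conducted.

Two tie conventions had to be fixed where the definitions are silent. A
locoregional event at exactly the time of a competing event counts as an
event (events take precedence over censoring at equal times — the usual
first-event convention). In the fixed-horizon analyses
(`censor_at_horizon()`), an event exactly at the horizon is kept:
"censoring all patients at 3 years" is read as censoring those still at
risk beyond the horizon.

## The individual level: a two-stage censored copula model

Rank correlation between two censored times cannot be computed directly;
the package uses a semiparametric survival-copula model. Writing
$S_1, S_2$ for the marginal survivor functions of the surrogate and OS,
the joint survivor function is modelled as

$$P(X > x, Y > y) = C_\theta\{S_1(x), S_2(y)\},$$

with $C_\theta$ a one-parameter Archimedean copula. Estimation is in two
stages:

1. $S_1, S_2$ are estimated by Kaplan-Meier — no parametric assumption
   on the margins;
2. $\theta$ maximises the censored pseudo-likelihood with the margins
   plugged in. Each pair contributes according to its censoring pattern:
   the copula density $c_\theta(u,v)$ when both events are observed, the
   partial derivative $\partial C_\theta/\partial u$ (or $\partial v$)
   when one is censored, and $C_\theta(u,v)$ when both are.

$\theta$ maps to Kendall's $\tau$ in closed form (Clayton:
$\tau = \theta/(\theta+2)$; Gumbel: $\tau = 1 - 1/\theta$) and to
Spearman's $\rho$ through the functional
$\rho = 12\int\!\!\int C_\theta(u,v)\,du\,dv - 3$, evaluated by 64-node
Gauss-Legendre quadrature per axis (accurate far beyond the reported
precision; the quadrature is verified against Monte-Carlo evaluation in
the test suite). The reported $\rho^2$ is the square of this Spearman
coefficient.

**Family choice.** The literature behind this class of models does not
pin down a single family, so the family is an explicit, reported
configuration: Clayton (lower-tail dependent, the default) and Gumbel
(upper-tail dependent) bracket the plausible dependence shapes, with
independence as a degenerate reference. The family is never estimated
silently.

**Numerical choices.** The optimisation runs on $\log\theta$ over
$\theta \in [10^{-3}, 50]$ (Clayton) or $[1+10^{-6}, 50]$ (Gumbel) with
tolerance $10^{-8}$ on the pseudo-log-likelihood; estimates within
$10^{-3}$ of a bound are flagged as boundary cases (near-independent or
near-comonotone data, e.g. when almost every first event is a death).
Kaplan-Meier survival probabilities are clamped to
$[1/(2n),\,1-10^{-10}]$ before the copula evaluation so that the final
step of the curve never produces $\log 0$; all copula quantities are
computed on the log scale with shifted-exponential sums, so large
$\theta$ does not overflow.

**Confidence interval.** The CI for $\rho^2$ is a patient-level
nonparametric bootstrap (200 replicates by default, percentile method,
margins and copula refitted in every replicate). With tens of thousands
of patients a rank-correlation CI is extremely narrow — which is why
published intervals at this scale often collapse to the point estimate
at two decimals — so nothing beyond an assumption-light bootstrap is
warranted. Replicates are configurable; the full-precision values are
always serialised.

## The trial level: weighted regression, STE, validation

Per-trial treatment effects are Cox partial-likelihood log hazard ratios
for the single covariate *arm*, with the Efron correction for ties (the
least-biased common default) and model-based standard errors from the
inverse observed information. Trials in which all events fall in one arm
have a monotone partial likelihood and no finite estimate; they are
excluded from the trial-level regression with a warning naming them
rather than patched with a continuity correction.

The trial-level model is ordinary weighted least squares of
$\log \mathrm{HR}_T$ on $\log \mathrm{HR}_S$ with weights proportional
to trial size:

$$\log \mathrm{HR}_{T,i} = \alpha + \beta \log \mathrm{HR}_{S,i} + \varepsilon_i,
  \qquad \mathrm{Var}(\varepsilon_i) = \sigma^2 / w_i .$$

$R^2 = 1 - \mathrm{RSS}_w/\mathrm{TSS}_w$ is the trial-level surrogacy
coefficient; its CI is a trial-level bootstrap (2000 resamples,
percentile), which respects the small number of trials. Weights are
patient counts by default (the natural reading of "trial size"), with
event counts as an option; all results are invariant to rescaling the
weights. Estimation error in the per-trial log HRs is deliberately *not*
modelled (no measurement-error adjustment): plain size-weighted WLS is
the method this pipeline mirrors, and the adjusted meta-analytic model
is left as an explicit extension. The intercept is included by default;
an origin-forced variant is available by flag and then uses the
uncentred $R^2$ convention.

**Prediction intervals.** For a new trial at surrogate effect $x_0$ and
weight $w_0$, the classical WLS interval is
$\hat\alpha + \hat\beta x_0 \pm t_{K-2}\,
\sqrt{\hat\sigma^2 (1/\tilde w_0 + h_0)}$, with $h_0$ the leverage at
$x_0$ and $\tilde w_0$ the weight relative to the average trial in the
fit. The default new-trial weight is the weighted mean trial size — a
symmetric choice, reported with the output; leave-one-out prediction
uses the left-out trial's own size instead, because that size is known
(the alternative convention is available and documented).

**Surrogate threshold effect.** The STE is the largest surrogate hazard
ratio at which the upper 95% prediction limit for the OS log hazard
ratio still touches zero — i.e. the minimum surrogate benefit a future
trial must demonstrate for a non-zero OS benefit to be predicted. It is
found by root-finding (tolerance $10^{-10}$) over
$\mathrm{HR}_S \in [0.2, 1.5]$; if the upper limit never crosses zero in
that bracket, or the fitted slope is non-positive, the STE is reported
as undefined with the reason. With zero residual variance the interval
collapses and the STE degenerates to the point where the fitted line
crosses zero (1.0 for an identity line through the origin).

**Leave-one-trial-out.** Each trial is left out once, the weighted
regression is rebuilt on the rest, and the left-out trial's observed OS
effect is compared with the 95% prediction interval at its surrogate
effect. The headline summary is the containment count ("m of K trials
inside"). At 20 trials the containment fraction of a correctly specified
model fluctuates around the nominal 95%; the package's own acceptance
band for simulation checks is [0.90, 0.99] across replicates, reflecting
finite-$K$ variability rather than a claim of exact coverage.

**Fixed horizons.** `sensitivity_fixed_horizon()` censors every
surrogate observation at one horizon (3 years for DFS, 2 for PFS in the
motivating design) and every OS observation at another (5 years), then
recomputes the per-trial effects and the regression. Infinite horizons
reproduce the unrestricted analysis bit-for-bit. When most surrogate
events fall before the horizon (around 80% in adjuvant lung-cancer
data), the restricted $R^2$ stays close to the unrestricted one — the
empirical basis for reading treatment effects early.

## The synthetic-data generator

Real individual-patient meta-analysis data are not publicly deposited,
so the generator is a first-class module with known ground truth at both
levels:

* Per-trial effects $(a_i, b_i)$ on the surrogate and OS hazards are
  bivariate normal with configurable means, SDs and correlation; the
  squared correlation is the trial-level $R^2$ in the error-free limit.
* Within a patient, a dependent uniform pair from the configured copula
  (Marshall-Olkin frailty construction: gamma frailty for Clayton,
  positive-stable for Gumbel) is inverted to exponential event times
  with arm-specific hazards $\lambda e^{\,\mathrm{arm}\cdot\log HR_i}$.
  Exponential margins keep hazard ratios constant over time, matching
  the proportional-hazards estimation downstream.
* Censoring is independent exponential drop-out plus an administrative
  horizon; all times are in years.
* One master seed; each trial draws from its own deterministically
  derived substream, so increasing the number of trials never reshuffles
  the earlier trials, and output is bit-identical across runs.

Two generators share this machinery. `simulate_meta_analysis()` emits a
*stylised two-margin world*: the surrogate margin is recorded as the
distant-event time irrespective of death, so the copula $\tau$ and each
trial's drawn log HRs are directly recoverable — this is the calibration
bench for the estimators. `simulate_event_history()` is the realistic
one: a latent first-progression time (split into locoregional and
distant components, with a second event of the other type following at
an exponential gap) is coupled to a baseline death time by the copula,
and after progression the death hazard increases additively by an
`excess_hazard` parameter (an illness-death acceleration). Progression
events are only recorded when they precede death and censoring, which
gives the composite-endpoint and locoregional-censoring rules real work
to do. The latent pairs are attached as an attribute so calibration
tests can compare against the configured association.

The event-history dependence between progression and death is not
observable from published summaries; the excess-hazard construction is
this package's modelling choice, and it is deliberately simple. What the
generator does *not* emulate: recruitment calendars, interval-censored
assessment schedules, cause-specific death, non-proportional hazards, or
informative censoring. Passing tests on these simulations therefore
demonstrate that the estimators recover the structure they assume — not
that real registry data satisfy those assumptions.

**Default study conditions.** Defaults mirror a mature adjuvant-style
meta-analysis: ~10 trials of ~200 patients, baseline hazards of
0.25/year (progression) and 0.18/year (death), drop-out censoring at
0.05/year with a 10-year administrative horizon (giving event fractions
in the 80-95% range), within-patient $\tau = 0.5$, mean log hazard
ratios of $-0.2$/$-0.15$, between-trial effect SDs of 0.15 and
trial-effect correlation 0.9. The parameter-recovery experiments in the
test suite use the scales at which the recovery properties are stated —
5000 pairs for the copula ($\pm 0.05$ on $\tau$), and 200 replicates of
30 trials × 2000 patients for trial-level $R^2$ with between-trial SDs
of 0.4, chosen so that within-trial Cox error
($\mathrm{se} \approx \sqrt{4/2000} \approx 0.045$) stays small relative
to the between-trial signal and attenuation does not mask the target
($R^2 = 0.9025$ at correlation 0.95).

## Worked example

```{r example}
cfg <- simulation_config(
  n_trials = 8, patients_per_trial = 250,
  copula_tau = 0.5, excess_hazard = 0.4,
  trial_effect_correlation = 0.95, seed = 5
)
records <- simulate_event_history(cfg)
report <- build_report(records,
  surrogate = "dfs",
  n_boot_individual = 50, n_boot_trial = 500, seed = 9
)
report
```

The fitted objects follow broom conventions:

```{r tidy}
tidy(report)
glance(report$trial)
```

and each result type has a plot:

```{r plots, fig.width = 6, fig.height = 4}
autoplot(report$trial)
autoplot(report$loo)
```

## Known limitations

* The copula family is an assumption, not an estimate; a badly
  misspecified family biases $\tau$ and $\rho^2$ (the test suite
  quantifies recovery only under the correct family).
* Plain WLS ignores the sampling covariance of the estimated log hazard
  ratios; with small trials the trial-level $R^2$ is attenuated.
* Locoregional control is handled by censoring at distant progression
  and death, as in the motivating analyses; under a competing-risks
  reading the estimand would differ.
* The bootstrap CIs are percentile intervals; at very small numbers of
  trials they can be wide and asymmetric, which is a faithful reflection
  of the information available.
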