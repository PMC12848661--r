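---
title: "Methods: recurrent hospitalizations and death as a multistate process"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recurrent hospitalizations and death as a multistate process}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recmstate)
```

## The model

`recmstate` analyzes event histories of the kind produced by heart-failure
trials: each subject starts at home, may be hospitalized and discharged
repeatedly, and may die at any point; follow-up can end in right-censoring.
We encode this as an illness-death process with recovery on the state space
{0 = at home, 1 = in hospital, 2 = dead}, with transitions 0→1, 0→2, 1→0,
1→2 and death absorbing. The *progressive* view relabels states by the
cumulative event count (R1, H1, R2, H2, ..., D); both views are projections
of one record set, so the package stores a single counting-process layout —
one row per sojourn, `(id, from, to, start, stop, status)` plus covariates,
with the half-open occupancy convention that a subject occupies `from` on
`(start, stop]`. Censoring is a status flag, never a state.

The transition hazard λ<sub>hj</sub>(t) is the instantaneous rate of moving
from h to j given occupancy of h just before t. Whether it may also depend
on the earlier path is exactly the Markov question: under the Markov
assumption the hazard depends on the past only through the current state
and time. When the assumption fails but censoring is *random* (independent
of the event process), the same estimators target *partly conditional
rates* — population-averaged rates conditioning only on the current state —
and the marginal summaries below retain a causal interpretation in a
randomized trial. When censoring is merely *independent* but
state-dependent, partly conditional rate estimation is biased; quantifying
that bias is one purpose of the simulation study shipped with the package.

## Nonparametric estimators

All estimators are exact right-continuous step functions
(`step_function()`); no smoothing or interpolation is applied anywhere.

* **Nelson–Aalen** (`nelson_aalen()`): cumulative hazard or partly
  conditional rate of one transition, summing (transitions at t) / (risk
  set in the origin state just before t). Risk sets are predictable (left
  limits): a subject transitioning at t is still at risk at t. Ties across
  subjects are pooled into one jump.
* **Kaplan–Meier** (`kaplan_meier()`): product-limit survival for
  first-event analyses, via `survival::survfit()`.
* **Aalen–Johansen** (`aalen_johansen()`): transition probabilities as the
  finite matrix product of I + ΔΛ̂(u) over observed transition times, the
  diagonal of each increment matrix set to minus the off-diagonal row sums;
  every partial product is checked to be a stochastic matrix (row sums
  within 1e-10 of one). Started at s = 0 it yields the state occupation
  probabilities Q̂<sub>l</sub>(t) (`state_occupation()`), which remain
  consistent without the Markov assumption under random censoring.
* **Marginal mean number of hospitalizations** (`marginal_mean()`):
  μ̂(t) = Σ<sub>u≤t</sub> Q̂₀(u−) ΔΛ̂₀₁(u). The left limit of the occupation
  probability is deliberate: it makes the estimator collapse *exactly* to
  the mean observed event count when no one is censored, which the test
  suite asserts at machine precision.
* **Average length of stay** (`average_length_of_stay()`): the exact
  integral of the hospital occupation probability over [0, t] — expected
  hospital days by t.
* **RR(t)** (`rr_ratio()`): between-arm ratio of expected hospitalizations
  per expected day alive, μ̂(t) / ∫₀ᵗ (1 − Q̂₂). A value below one means
  fewer admissions per unit lifetime under treatment.
* **Uncertainty**: basic bootstrap limits
  (2θ̂ − q<sub>1−α/2</sub>, 2θ̂ − q<sub>α/2</sub>) from resampling
  *subjects* (clusters), not records, preserving within-subject dependence
  (`basic_bootstrap_ci()`). Closed-form (Greenwood-type) variances are not
  provided; the bootstrap is the single uncertainty route for the
  nonparametric summaries.

## Semiparametric engines

`cox_fit()` is a from-scratch Newton–Raphson maximizer of the stratified
Breslow partial likelihood on counting-process data. One engine covers the
cause-specific Cox model, the Andersen–Gill (AG) model for recurrent
home→hospital transitions, and the Prentice–Williams–Peterson (PWP) model
(strata = number of previous hospitalizations, total-time scale — the
gap-time variant is deliberately not implemented). Design choices:

* **Risk sets**: a row is at risk at an event time t in its stratum when
  start < t ≤ stop; subjects therefore leave the hospitalization risk set
  while in hospital.
* **Ties**: Breslow approximation. Simulated times are continuous, so ties
  only arise in user data; Breslow is the simplest consistent choice.
* **Iteration**: at most 25 Newton steps with step-halving on overshoot;
  convergence when the relative log-likelihood change falls below 1e-9. A
  step that cannot reach a finite likelihood stops the iteration; diverging
  coefficients (|β| > 15) or a singular information matrix set the
  `monotone` flag rather than failing silently.
* **Variance**: both the model-based inverse information and the robust
  cluster sandwich (subject-level sums of score residuals) are returned.
  All treatment and Markov-probe tests in the experiment pipeline use the
  robust variance; the model-based one is available by flag. For recurrent
  events the robust choice is standard, and on independent single-record
  data the two agree asymptotically (tested).
* **Baseline**: Breslow cumulative-hazard increments per stratum.

`ghosh_lin_fit()` implements the proportional *rates* model for the
recurrent-event process stopped at death: deceased subjects remain in the
risk population, and the unobservable at-risk indicator under censoring is
reconstructed by inverse-probability-of-censoring weights from a
Kaplan–Meier estimate of the censoring distribution (pooled across arms by
default, per-arm by flag; censoring is arm-independent in every simulation
scenario). If the censoring survival estimate hits zero before the last
recurrent event the fit stops with an error — weight trimming and multiple
imputation of censoring times are intentionally out of scope. Because the
weights grow like the inverse censoring survival, the latest events can
dominate the estimating equation when censoring is heavy; the `horizon`
argument restricts estimation to events before a chosen time, the standard
stabilization, and the analysis scripts use it. The sandwich
variance treats the estimated weights as fixed; with no deaths and no
censoring the estimating equation coincides with AG's, which the tests
verify to 1e-8. Wald tests (`wald_test()`) use the normal reference,
two-sided.

## Markov diagnostics and the experiment pipeline

`augment_markov_covariate()` attaches to every at-home interval the number
of completed hospitalizations before its start and its start time (the
entry time into the current at-home state, in days). A significant Wald
effect of either covariate indicates history dependence, i.e. a Markov
violation. The scenario-to-model mapping is fixed: AG with the count probe
for the illness-death scenarios 1–4, PWP with the entry-time probe for the
progressive scenarios 5–9; *model 1* is treatment + probe, *model 2*
treatment only. `run_scenario()`, `table_rejections()` and `power_run()`
count 5%-level rejections over replications. Replications whose fit does
not converge or is flagged monotone count as non-rejections and are
reported in a `failures` column — conservative and visible. Each
replication's random stream is derived deterministically from
(seed, scenario, replication), so any single replication can be reproduced
in isolation and results do not depend on execution order.

## The simulator

`simulate_dataset()` generates trials of 600 subjects (300 per arm,
assigned by permutation, not by coin flips — the design fixes the group
sizes) as a nested series of competing-risks experiments: within each
sojourn the active cause-specific rates are constant, the waiting time is
exponential in their sum, and the cause is multinomial in their ratios.
Hospital sojourns are drawn on the clock-reset (waiting-time) scale, which
for constant rates coincides with calendar-time simulation. Baseline
per-day rates are 0.002 (home→hospital), 0.0007 (home→death), 0.004
(hospital→home), 0.00075 (hospital→death; 0.0011 in scenario 9). The nine
scenarios cross three ingredients:

* **Structure**: illness-death (scenarios 1–4) vs. progressive (5–9), the
  latter multiplying every transition hazard by (1 + 0.1 × number of
  previous states).
* **Markov violation**: a subject-level frailty L ~ Gamma(shape 2,
  scale 1) multiplying all transition hazards (scenarios 2, 4, 6, 8), or
  entry-time-dependent hazards (scenario 9).
* **Censoring**: one exponential(0.00045) time drawn up front
  (random censoring; the path is truncated if it arrives before death), or
  a third competing cause with hazard 0.00045 × (1 + 0.05 × number of
  previous states) in every non-terminal state (state-dependent
  censoring). The frailty never touches the censoring rate — that is what
  keeps censoring *random* in scenarios 2 and 6. No administrative study
  horizon is applied on top.

Under the treatment alternative the treated arm's home→hospital hazard is
multiplied by exp(−0.1625), a hazard ratio of 0.85.

**Scenario 9's entry-time factor.** The printed factor (entry time into
the current state / 1000) is zero for the initial state, entered at time 0,
which would make the first sojourn infinite. We resolve this by drawing the
first home sojourn at the baseline rates and applying the literal factor
entry/1000 from the first transition onward. We initially considered the
gentler resolution (1 + entry/1000), but it weakens the entry-time signal
so much that the PWP probe rejects in only ~40% of replications — far from
the saturated detection this scenario is designed to exhibit — so the
literal-factor resolution is used.

**Consequences of the frailty convention.** A Gamma(2, 1) hazard
multiplier has mean 2, so the frailty scenarios run "faster" than their
Markov counterparts: they carry fewer censored subjects (~170–200 per 600
instead of ~220–250) and heavier event loads, and the population-averaged
home→hospital rate starts near 0.004/day and only drops below the Markov
line 0.002 t at t ≈ 3500 days (the frailty-selection effect). A mean-one
frailty would leave the early rate at 0.002/day; we follow the explicit
hazard formula as printed. Scenario 9's slow early dynamics under the
literal entry factor push its mean censored count up to ~280. The analysis
scripts report these loads rather than hiding them.

**What the generator does and does not emulate.** It reproduces the
structural features of a long-running heart-failure trial — two randomized
arms, recurrent admissions with discharges, a terminal death state, heavy
right-censoring, up to ~8–12 admissions for the most event-prone subject
per trial. It does not emulate covariate-dependent risks beyond treatment,
seasonal or calendar-time effects, within-hospital duration dependence,
interval censoring, left truncation, or event-driven (administrative)
censoring. Tests passing on these data therefore validate the estimators'
internal consistency and their behavior under the stated censoring and
history-dependence mechanisms — not robustness to everything real data can
do.

## Numerical choices and degenerate inputs

Zero-length sojourns within a subject are rejected at validation
(continuous simulation makes them measure-zero; real data should resolve
them before import), while ties across subjects are pooled. An empty
transition type yields the zero step function. `draw_sojourn()` refuses an
all-zero rate vector (the sojourn would be infinite). Aalen–Johansen
construction asserts stochasticity of every partial product. The Ghosh–Lin
IPCW weights error out, with guidance, when the censoring Kaplan–Meier
reaches zero too early. Times are days since randomization throughout; the
partial likelihood is rank-based, so rescaling the time unit leaves
coefficients unchanged (tested), and rescaling the entry-time covariate
rescales its coefficient without changing its Wald test.

## Problem sizes

The shipped test suite runs the study at reduced, fixed-seed sizes chosen
as the smallest that make each claim statistically meaningful: saturation
checks at 60 replications, nominal-level checks at 200 replications
against central 99.9% binomial bands, power and bias-curve checks at
100–200 replications with explicit Monte-Carlo allowances, and exact
identities on 6–150-subject fixtures. `scripts/acceptance.R` recomputes
the headline rejection counts at the full 1000 replications per scenario
and the load summaries at 200 datasets per scenario; the reduced-size grid
in `analysis/04_markov_tests.R` accepts a replication count as an
argument.

## Known limitations

Fine–Gray subdistribution regression, proportional-odds and pseudo-value
regression, frailty/random-effects regression, gap-time PWP, weight
trimming, multiple imputation of censoring times, landmark (s > 0)
non-Markov transition-probability estimators, and alternative Markov tests
(e.g. landmark or log-rank based) are out of scope. The Ghosh–Lin variance
ignores the sampling variability of the estimated censoring weights, which
is slightly conservative in the settings simulated here. The paper-scale
study conditions are fixed in `scenario_catalog()`; they are study
definitions, not tuning knobs.
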