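---
title: "Bayesian longitudinal selection models for cost-effectiveness analysis with informative missing data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian longitudinal selection models for cost-effectiveness analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceamiss)
```

## The problem

Trial-based cost-effectiveness analyses (CEA) collect health-related quality
of life (HRQoL) at repeated timepoints and costs over the follow-up period.
In long follow-ups much of the HRQoL data goes missing, and in two distinct
ways: *interim missingness* (a skipped questionnaire with later observations)
and *loss to follow-up* (nothing observed from some timepoint onward).  The
reasons for the two can differ, and either can depend on the patient's
unobserved health at the time — the data may be *missing not at random*
(MNAR).  Because no analysis can verify the missingness mechanism from the
observed data alone, the defensible strategy is a sensitivity analysis over a
set of clearly stated, contextually plausible mechanisms.

`ceamiss` implements a fully Bayesian selection-model framework for this
setting.  One joint model couples:

* a **hurdle-gamma longitudinal model** for HRQoL decrements,
* a **conditional gamma model** for 5-year total costs,
* a **truncated-gamma imputation model** for missing baseline HRQoL,
* a **three-category multinomial-logistic missingness model** that
  distinguishes interim missingness from loss to follow-up, and
* a **CEA outputs layer** (recycled predictions, incremental net benefit,
  acceptability curves) consuming the joint posterior.

Everything is estimated in one MCMC run, so the uncertainty from imputing
missing outcomes, costs and baseline covariates propagates into the
cost-effectiveness conclusions.

## Outcome scale and the analysis model

Utilities `u` (1 = full health) are converted at load time to decrements
`q = 1 - u`, so all sub-models share one positive-ish scale.  EQ-5D-style
data show a spike of values at exactly full health, which a continuous
distribution cannot represent; the primary family is therefore a hurdle:

* `h_it ~ Bernoulli(p_it)` with `logit(p_it) = gamma_t + omega' (bq_i,
  bmi_i, age_i, sex_i)` — the probability of full health (`q_it = 0`);
* `q_it | h_it = 0 ~ Gamma(shape.q, shape.q / mu.q_it)` with
  `log(mu.q_it) = alpha_t + theta_i + beta' (bq_i, bmi_i, age_i, sex_i)`;
* `theta_i ~ Normal(0, theta.sigma^2)` are patient random intercepts on the
  gamma part only: the hurdle is kept marginal, which is both harder to
  overfit and consistent with how the spike behaves empirically.

Plain-gamma and normal variants with the same linear predictors are provided
for the model-selection step (`compare_families()`); the gamma variant uses
the positivity-shifted decrement `1 - u + 1e-4`, the shift applying *only*
there — a hurdle with a shifted zero point would be vacuous.  Every
parameter block exists once per treatment arm, indexed by the arm actually
*received*; intention-to-treat estimates are recovered later by the recycled
predictions (below).  Age and BMI are centred at their sample means before
entering any linear predictor (this is a sampler-geometry choice; it changes
only the meaning of intercepts).

Six-timepoint decrements aggregate into 5-year QALYs by the
area-under-the-curve trapezoid

```
Q = 0.5 (1 - q1) + 0.875 (1 - q2) + (1 - q3) + (1 - q4) + (1 - q5) + 0.5 (1 - q6)
```

with timepoints at 3 months and years 1–5 (baseline is held separately and
enters as a covariate, not as a seventh term).

Total 5-year costs follow a conditional gamma regression,

```
c_i ~ Gamma(shape.c, shape.c / v.c_i)
log(v.c_i) = zeta' (1, bmi_i, age_i, sex_i) + xi (Q_i - mu.Q_i)
```

where `mu.Q_i` is the model's expected QALY for patient `i`.  The
`xi`-coupling to the QALY residual is what induces cost–outcome correlation;
`xi = 0` recovers independent endpoints.  Marginal (covariate-only) cost
means, `exp(zeta' x)`, are used for prediction.  A patient with some but not
all annual costs observed contributes a latent total bounded below by the
sum of the observed annual costs (a lower-truncated gamma node); the bound
is never applied to fully observed totals.

`mu.Q_i` is built from expectation-mode predictions `(1 - p_it) mu.q_it`
rather than from Bernoulli draws of the hurdle: the plug-in mean is the
quantity the cost residual needs, and drawing would only inject extra noise
into the cost likelihood.  A stochastic prediction mode is exposed for
posterior-predictive work.

Missing baseline decrements are imputed from `Gamma(shape.bq, rate.bq)`
truncated above at 1.2, the largest viable EQ-5D decrement.

## The missingness model and the sensitivity grid

Each patient-timepoint gets a category `m_it`: 1 observed, 2 interim
missing, 3 loss to follow-up (LTFU).  Interim vs LTFU is decided by whether
any later timepoint is observed; a patient missing everything is LTFU from
the first timepoint.  The model is multinomial-logistic with category 1 as
reference:

```
log(phi_itr) = kappa0_tr + kappa_r' (bmi, age, sex, previous.q) + lambda_r * change.q,   r = 2, 3
```

with per-timepoint intercepts, the previous decrement (baseline at t = 1) as
a covariate, and `change.q` the change in HRQoL *utility* since the previous
timepoint (`previous decrement - current decrement`, positive = health
improved).  With that sign convention `lambda = log 2 = 0.69` literally
encodes a doubling of the missingness weight per unit utility improvement,
and positive selection yields imputations *above* their MAR values.  Because
`change.q` involves the possibly unobserved current decrement, a nonzero
`lambda` makes the mechanism MNAR and ties the missingness model to the
latent outcomes; `lambda` is never estimated — it is fixed by a point prior
and varied across scenarios:

| scenario | MM interim | MM LTFU | LS interim | LS LTFU |
|---|---|---|---|---|
| MAR   | 0 | 0 | 0 | 0 |
| MNAR1 | −0.69 | −0.69 | +0.69 | +0.69 |
| MNAR2 | +0.69 | +0.69 | −0.69 | −0.69 |
| MNAR3 | 0 | −0.69 | 0 | +0.69 |
| MNAR4 | 0 | +0.69 | 0 | −0.69 |
| MNAR5 | −0.69 | 0 | +0.69 | 0 |
| MNAR6 | +0.69 | 0 | −0.69 | 0 |
| MNAR7 | −0.69 | −0.69 | −0.69 | −0.69 |
| MNAR8 | +0.69 | +0.69 | +0.69 | +0.69 |

`CCA` restricts to complete cases and omits the missingness model entirely.
Custom quadruples are accepted via `custom_scenario()`.

Two conventions here are genuinely open and are decided as follows.  First,
the scale of `change.q`: written with decrements the same coefficient would
flip its qualitative meaning; we define it on the utility scale so that the
published direction ("positive selection, imputations higher") and the
odds-doubling interpretation both hold simultaneously.  `previous.q` stays
on the decrement scale (flipping it would only flip the sign of its
coefficient, which is estimated).  Second, dropout is treated as absorbing:
multinomial contributions stop at the first category-3 event.  Including
deterministic post-dropout categories would distort the time-intercept
estimates without adding information.

Cost missingness is treated as MAR throughout (administrative in origin);
the framework hook for a cost-side selection model exists in the factorized
likelihood but is deliberately not implemented.

## Inference

The joint posterior is sampled with JAGS (Gibbs/slice sampling) via `rjags`.
The hurdle likelihood of observed cells enters through the standard
zeros-trick; each missing decrement is a pair of latent nodes (a Bernoulli
full-health indicator and a gamma positive part), each partially observed
total cost a lower-truncated gamma node, and each missing baseline a
truncated gamma node.  Imputed decrements are restricted to the viable
EQ-5D decrement range (at most 1.6, i.e. utility at least −0.6), mirroring
the 1.2 bound on baseline decrements.

Priors: `Normal(0, 10^2)` on regression coefficients, time intercepts and
`xi`, half-normal `(0, 5^2)` on `theta.sigma`, half-normal `(0, 10^2)` on
the gamma shapes.  The random-intercept mean is fixed at 0 and
absorbed into the time intercepts — estimating both is only weakly
identified.  Defaults are 2 chains × (500 adapt + 500 burn-in + 1000 draws);
every analysis in the test-suite states its own (smaller) problem sizes, and
those choices — down to 1 chain × a few hundred draws on datasets of 150–300
patients — were made on pilot R-hat behaviour, not per-analysis.

Numerical guards, stated because they are deliberate: the exponentiated
linear predictors for the gamma means are capped (`exp(min(max(eta, -20),
7))` for decrements, upper bound 23 for costs) and predicted decrements
entering `mu.Q` are clamped to the viable range.  Without these, a transient
excursion during adaptation can push `mu.Q` off scale, the cost conditional
flattens against the cap, and the sampler is left on a plateau it cannot
leave.  All caps sit far outside the data-supported region and are inactive
at the posterior; the R-side density layer (used for DIC and checks) applies
the same clamp to predicted decrements and none elsewhere.

Diagnostics: `convergence_report()` gives split-R-hat and effective sample
sizes with a 1.05 flag threshold.  `compute_dic()` reports `Dbar + pD` per
likelihood component with latent quantities plugged in at their draws
(posterior means for the plug-in deviance); hurdle-family HRQoL DICs also
model the spike and are flagged as not comparable with gamma/normal-family
ones.  Components with plugged-in latent data can show mildly negative `pD`
— a known artifact of conditional DIC, left visible rather than masked.
`brute_force_posterior()` is a direct-summation grid oracle used in tests to
validate the MCMC path on tiny models, and `posterior_predictive_check()`
compares replicate-data statistics (spike share, per-timepoint means, cost
mean and skewness) with their observed values.

## CEA outputs

`recycled_predictions()` predicts, for every posterior draw, each patient's
QALYs and costs from baseline covariates under assignment to MM and then to
LS.  Crossover is handled by the intention-to-treat rule: a patient who
crossed over is predicted with the parameters of the arm actually received
under *both* assignments, so randomization does not change their prediction
— it only tells us how to average.  Incremental QALYs and costs are means of
per-patient differences; `incremental_net_benefit()` computes
`INB = wtp * dQ - dC` draw-wise (default willingness to pay 20,000 GBP/QALY)
and `ceac()` evaluates `P(INB > 0)` over a grid (default 0–50,000 by 1,000).
Probabilities split ties at 0.5 so degenerate equal-arm cases sit at 1/2.

For population-level predictions the patient random intercept is integrated
out analytically — the gamma-part mean acquires the lognormal factor
`exp(theta.sigma^2 / 2)` — rather than simulated, which removes Monte-Carlo
noise from the estimand; a draw-based mode is available.  Predicted costs
use the marginal mean (no gamma noise is added): incremental *means* are the
estimand, and predictive noise would only widen intervals without moving
them.

The per-year QALY table needs a year-level decomposition of the trapezoid,
which the aggregate formula does not dictate.  We use Year 1 =
`0.5 (1-q1) + 0.875 (1-q2)`, Years 2–4 = `(1-q_{t+1})`, Year 5 =
`0.5 (1-q6)`, so the rows sum to the 5-year total by construction.  This is
a reporting convention of this package, stated rather than inferred.

## The synthetic-trial generator

Real data of this kind are not publicly deposited, so
`default_reflux_like_config()` defines a fixed synthetic study in which
every downstream stage is testable against known truth.  Its defaults *are*
the study conditions: 357 patients; crossover 37.6% (LS to MM) and 5.6%
(MM to LS); a utility spike at 1 of about 0.22; mean utilities declining
from roughly 0.76 to 0.65 (LS) and 0.70 to 0.64 (MM); right-skewed costs
around 3,500 GBP (LS, shape 3) and 1,200 GBP (MM, shape 2); cost–QALY
correlations about −0.42 in MM (`xi = -0.6`) and −0.08 in LS
(`xi = -0.1`); 3.6% missing baselines; 10% per-year cost deletion
(administrative MAR); and multinomial missingness intercepts frozen at
values calibrated once (by `calibrate_missingness_intercepts()`) to
patient-level rates of 19.3% interim-only, 24.9% LTFU-only and 7.6% both.
Hitting all three rates requires interim missingness to decline over
follow-up while the dropout hazard rises (time slopes −0.3 and +0.9 on the
log-odds scale) — with flat hazards the two pattern types cannot co-occur
often enough.  The generative selection coefficients are zero; dropout
depends on the *true* previous decrement, so datasets still carry a mild
non-ignorable channel whenever that decrement is itself missing, which is
exactly what the missingness sub-model is for.

The generator draws complete outcomes first, then the missingness process,
then deletes.  Because only the 5-year total cost is modelled, annual costs
exist solely to exercise the partial-cost truncation machinery; the total is
split by fixed proportions (0.6, 0.1, 0.1, 0.1, 0.1 for LS, reflecting
up-front surgery; uniform for MM) — an invented, documented device.

What the generator does *not* emulate: real covariate distributions beyond
plausible ranges, item-level EQ-5D responses, serial correlation beyond the
shared random intercept, cost–HRQoL missingness dependence, or
administrative censoring patterns.  Tests passing on this generator
demonstrate internal validity of the machinery (parameter recovery,
direction of selection effects, interval behaviour), not performance on any
real trial.

## Worked example

```{r example, eval = FALSE}
sim <- generate_dataset(default_reflux_like_config(n_patients = 357, seed = 1))
ds  <- sim$dataset
summarize_missing_patterns(ds)

fit_mar   <- fit_scenario(ds, "MAR",   chains = 2, seed = 1)
fit_mnar1 <- fit_scenario(ds, "MNAR1", chains = 2, seed = 2)

res <- lapply(list(fit_mar, fit_mnar1), function(f)
  cea_result(recycled_predictions(f), wtp = 20000))
scenario_compare(res)
```

Or end to end from the shell:

```sh
Rscript inst/cli/ceamiss.R simulate --n 357 --seed 1 --out out/
Rscript inst/cli/ceamiss.R scenarios --data out/data.csv \
  --scenarios CCA,MAR,MNAR1,MNAR2 --seed 1 --out out/
```

## Known limitations

* Inference cost grows with the number of latent nodes; full-scale fits with
  the missingness model take minutes, not seconds.
* DIC for the hurdle family is not comparable across families (flagged in
  output); WAIC is not currently reported.
* The framework models HRQoL-side MNAR only; costs are assumed MAR.
* Scaled-beta and mixture HRQoL families, survival/time-to-event endpoints,
  and expert elicitation of selection priors are out of scope; the family
  argument and `custom_scenario()` are the extension points.
* `lambda` is a point prior by design; a continuous prior would require
  informative elicitation to be identifiable and is not exposed.
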