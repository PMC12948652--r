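---
title: "The prevalent new-user design in pnucohort: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The prevalent new-user design in pnucohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pnucohort)
```

## Why a prevalent new-user design

When a new drug class enters the market, restricting a comparative safety
study to first-ever users of each drug (the active comparator new-user
design) can leave too few exposed patients, and it excludes the clinically
common pathway of *switching* from the established comparator to the new
drug. The prevalent new-user (PNU) design enrolls both incident initiators
and switchers, and restores comparability by matching each study-drug user
to a comparator user with similar *prior use of the comparator* at the
moment of initiation. `pnucohort` implements that design end to end.

## The model and its assumptions

### Exposure sets

For a study-drug user with `k` prior comparator prescriptions, time since
base-cohort entry `t` (days) and index calendar year `y`, the exposure set
holds comparator *index prescriptions* — each comparator patient is
represented by the specific prescription under consideration, with its own
prior count, time since that patient's entry, and year. Three definitions
are supported: prescription-based (`k` equal), time-based (`|Δt| ≤ caliper`,
inclusive), and hybrid (all three predicates). A comparator patient may
appear in many sets, and several times in one set through different
prescriptions; uniqueness is enforced at matching, mirroring risk-set
sampling.

Internally a set is never materialized as rows: each definition selects a
contiguous range of one sorted candidate table (binary search on the
time-since-entry scale within prior-count/year groups). The sum of pool
sizes grows roughly quadratically with cohort size — tens of millions of
implied member rows for a cohort of twenty thousand patients — while the
range representation stays linear, which is what makes the Monte-Carlo
calibration studies in the test suite feasible on one CPU. A treated user's
own pre-switch prescriptions are masked from their own pool.

### The time-conditional propensity score

Treatment assignment is modelled conditionally on exposure set with a
conditional-logit likelihood. To bound the cost of fitting, each set
contributes a random sample of about `target_per_set` comparators (default
50), and each sampled comparator carries the inverse of its set's sampling
fraction as a weight. We place those weights in the denominator of the
conditional likelihood only,

$$\ell(\beta) = \sum_s \Big[\eta_{T(s)} - \log\big(e^{\eta_{T(s)}}
  + \sum_{j \in s} w_j e^{\eta_j}\big)\Big], \qquad \eta = x^\top\beta,$$

so the sampled rows stand in, in expectation, for the full denominator sum
while every treated row (weight 1) keeps its own contribution. This is a
design choice: the placement of sampling weights in a conditional likelihood
admits alternatives, so the expression is isolated in one routine
(`tcps_loglik()` / the internal `clogit_derivs()`) to make substitution
easy. The log-likelihood is concave; with the per-set sampling fraction
forced to 1 the fit coincides bitwise with the no-sampling fit, and at unit
weights it agrees with `survival::clogit()` to optimizer precision (both
facts are asserted in the test suite).

Scores for *all* members — sampled or not — are `plogis(xβ)`. Matching and
positivity compare scores only within a set, so the missing set-level
intercept is immaterial; the logistic transform simply places scores on a
bounded, interpretable scale.

### Positivity, matching, follow-up

A set is dropped when the treated score lies outside the inclusive
`[min, max]` range of its comparator scores, evaluated once, before any
matching, on the full pool. (An alternative would re-check the range against
the candidates still available as matching consumes comparators; the
one-time pre-check matches the design's sequential description and keeps
the diagnostic interpretable as a property of the data rather than the
match order.)

Matching processes treated users in ascending index-date order (ties by
patient id) and picks the still-available candidate with the smallest
absolute score difference; exact ties go to the earlier candidate
prescription date, then the smaller patient id, making the output fully
deterministic. Without-replacement operates at the comparator-person level:
using a person's week-12 prescription in one pair removes their week-20
prescription from every other set, because reusing the person would double
their outcome person-time. No caliper is applied to the matched score
distance; the positivity screen is the only guard against poor matches. A
person matched as a comparator who is also a switcher remains eligible as a
treated user in their own set — switchers genuinely occupy both roles.

Follow-up is as-treated: from the index date to the earliest of outcome,
study end, death, the cirrhosis-analogue event, transfer, or treatment
discontinuation, where discontinuation is the end of the continuous
treatment episode containing the index date (last supply end + 30-day
grace) and, for comparators, also their switch to the study drug. Episode
intervals are half-open `[start, end)` on whole days, so boundary days are
never double-counted; an endpoint on the index date itself is given half a
day so survival times stay positive. When several causes coincide on one
day, the outcome takes precedence (the recorded order is outcome, study end,
death, cirrhosis, transfer, discontinuation).

Hazard ratios come from an unstratified Cox model on the treatment
indicator with Breslow tie handling and a robust sandwich variance —
clustering on the individual by default, with a matched-pair clustering
option (`cluster_by_pair`). The 1:1 matched contrast targets the average
treatment effect in the treated; subgroup estimates (incident, prevalent)
refit the model on the subgroup's records rather than using interactions,
so each subgroup's estimate is self-contained.

### Balance diagnostics

Balance is summarized as absolute standardized mean differences:
`|m_a − m_b| / sqrt((s_a² + s_b²)/2)` for continuous covariates, the
proportion analogue for binary ones, and for multi-level covariates the
Mahalanobis-type quadratic form over the non-reference level indicators, so
each covariate yields one number. Zero pooled variance with unequal means is
flagged as `Inf` rather than an error. The descriptive "unmatched
comparator" group is one candidate prescription drawn uniformly from each
nonempty exposure set before matching.

## What the synthetic generator emulates — and what it does not

`generate_population()` produces the structure the design assumes: staggered
entry over a five-year window (first prescriptions uniform over the window);
a newly introduced study drug whose uptake rises by calendar year (default
5% to 35%, so study initiators are the minority, as they are when a class is
new); covariate effects on the initiation choice (log odds-ratios on a
logit-shifted uptake curve); an exponential comparator-to-study switch clock
whose log-rate is linear in covariates, realized at the next prescription
issue; repeat prescriptions (28-day supplies, Poisson refill gaps, mean 4
days, 15% stop probability per refill) and independent exponential death,
transfer and cirrhosis-analogue clocks; and a piecewise-exponential outcome
whose hazard multiplies by `exp(true_log_hr)` from study-drug initiation
onward. Treatment is time-fixed from initiation, which keeps the marginal
as-treated hazard ratio equal to the configured value and gives closed-form
oracles for incidence. Ground truth (latent switch and outcome times, the
true effect) is written to a separate component/file the pipeline never
reads.

The default outcome rate, 5e-4 events per person-day, is deliberately higher
than real upper-GI-bleeding incidence: it is a desk-scale choice so that
cohorts of a few thousand patients yield enough events for stable Cox
estimates in tests. Refill-gap behaviour in primary-care data is not well
characterized; the Poisson default is a modelling choice exposed in the
configuration.

What the generator does *not* emulate: covariates are time-fixed (no
worsening disease prompting the switch, so the real-world channel by which
switching correlates with imminent outcomes is absent); there is exactly one
comparator and one study class; no dose information; refill behaviour is
homogeneous across patients; and censoring clocks are independent of
covariates. Passing tests therefore demonstrate that the *implementation*
of the design is correct and calibrated under its own assumptions — not
that the design removes confounding in real data, where informative
switching and residual confounding remain live concerns.

`confounded_scenario(strength, seed)` is the standard test bed: age, sex and
a comorbidity indicator drive choice (log-ORs 0.03/year, 0.5, 0.8 at
strength 1), switching (same), and the outcome (log-HRs 0.02/year, 0.4,
0.7), all scaled by `strength`; `strength = 0` is randomized treatment.

## Numerical choices

- **TCPS optimizer**: Newton–Raphson with step halving; convergence at
  max |score| < 1e-8, at most 100 iterations. Per-set log-sum-exp keeps the
  likelihood finite for extreme linear predictors. A singular information
  matrix triggers an automatic 1e-6 ridge retry; separation (score
  vanishing while coefficients diverge) is flagged as non-convergence
  unless a ridge is set. Columns with no within-set variation anywhere
  (e.g. calendar year under the hybrid definition, which conditions on it)
  are unidentified and dropped with a record.
- **Design encoding**: continuous covariates standardized; two-level and
  character covariates one-hot against the first level, with missing values
  as an explicit `missing` level; calendar year categorical. The encoding
  template is frozen at fit time and reused at prediction.
- **Episode merging**: a refill "continues" an episode when issued no later
  than the running supply end plus the grace period (the same 30-day gap
  that defines discontinuation); a strict supply-overlap mode is available
  (`bridge = "strict"`). The prior-prescription count uses a strict-before
  convention, so the index prescription is the (k+1)-th.
- **Determinism**: every stochastic step takes a seed; the pipeline splits
  stage seeds deterministically from one master seed, and identical calls
  reproduce reports exactly.
- **Problem sizes in the test suite** (the package's own choice of
  desk-scale study conditions): oracle equivalences on instances of up to 5
  sets × 5 rows and 20 survival records; matching invariants on 500 random
  instances; null calibration with 200 pipeline replicates at n = 2000;
  effect recovery (true hazard ratio 2) with 50 replicates at n = 20 000;
  balance restoration at n = 10 000.

## Known limitations

- The robust variance treats matched pairs as independent by default; the
  pair-clustered option is available but the two are not identical in small
  samples.
- Greedy chronological matching is not globally optimal; an optimal
  assignment could achieve smaller total score distance at the cost of
  determinism and the design's sequential interpretation.
- The positivity screen uses the score range only; a set can pass while all
  its close candidates are consumed by earlier matches.
- With very strong treatment uptake the comparator pool thins in late
  calendar years and balance degrades for the rarest covariate strata —
  a population-overlap failure no within-set matching can repair; the
  generator's defaults keep the study drug the minority option, as in the
  setting the design targets.
- Inverse-probability-of-censoring weighting, high-dimensional propensity
  scores, disease-risk scores and dose-based exposure-set criteria are out
  of scope.
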