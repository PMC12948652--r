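# pnucohort

Tools for **prevalent new-user (PNU) cohort studies** in longitudinal
prescription data. The PNU design extends the active comparator new-user
design by also enrolling *switchers* — patients who initiate a newly
introduced study drug after prior use of the established comparator — so
that treatment effects can be estimated in the full population a new drug
actually reaches. The package implements the complete design as a tested
pipeline, and ships a synthetic electronic-health-record generator with
known ground truth so that every stage can be validated without access to
proprietary claims or primary-care databases.

## The design

For patients, prescriptions and outcome events in three plain tables, the
pipeline performs:

1. **Base cohort assembly** — new users of either drug enter at their first
   in-window prescription, subject to a 12-month drug-free, registered
   washout; comparator users who later receive the study drug contribute an
   additional prevalent new-user (switcher) membership at the switch date.
2. **Exposure sets** — for each study-drug user with k prior comparator
   prescriptions, time since entry t and index year y, the pool of
   comparator index prescriptions that are comparable under one of three
   definitions: *prescription-based* (same k), *time-based* (|Δt| ≤ caliper,
   default ±30 days), or *hybrid* (same k, |Δt| ≤ caliper, same calendar
   year).
3. **Time-conditional propensity scores (TCPS)** — a conditional logistic
   model of treatment given covariates, conditional on exposure set, fitted
   on within-set samples of comparators (about 50 per set) weighted by the
   inverse sampling fraction:

   ```
   L(β) = Σ_s [ η_treated(s) − log( e^{η_treated(s)} + Σ_j w_j e^{η_j} ) ],   η = xβ
   ```

   Scores are then predicted for *all* members of every set.
4. **Positivity screening** — a set is dropped when the treated user's score
   falls outside the inclusive range of its comparator scores.
5. **Matching** — chronological 1:1 nearest-TCPS matching within exposure
   set, without replacement at the comparator-person level.
6. **As-treated follow-up and effects** — person-time from index date to the
   earliest of outcome, study end, death, cirrhosis-analogue censoring,
   transfer, or treatment discontinuation (supply end + 30-day grace;
   a comparator's switch also discontinues); hazard ratios from a Cox model
   with robust standard errors, overall and in the incident and prevalent
   new-user subgroups; covariate balance as absolute standardized mean
   differences (ASD) against the conventional 0.1 threshold, plus a random
   unmatched comparator sample for the descriptive contrast.

## Worked example

```r
library(pnucohort)

cfg <- confounded_scenario(strength = 1, seed = 7, n_patients = 5000)
sim <- generate_population(cfg)
sim
#> <pnu_sim> 5000 patients, 26764 prescriptions, 1696 events
#>   window: 2000-01-01 .. 2004-12-31  true log HR: 0

report <- run_pnu(sim$patients, sim$prescriptions, sim$events,
                  window = c(cfg$window_start, cfg$window_end),
                  definitions = c("prescription", "hybrid"), seed = 7)
report
#> <pnu_report> 2 configuration(s); base cohort:
#>   incident study 1016 | prevalent study 403 | comparator 3722
#>     definition caliper  subgroup               hr confidence_limit_ratio match_rate
#> 1 prescription      30   overall 1.01 (0.80-1.27)                   1.59      0.999
#> 2 prescription      30 prevalent 1.01 (0.65-1.57)                   2.42      0.999
#> 3 prescription      30  incident 1.00 (0.77-1.32)                   1.71      0.999
#> 4       hybrid      30   overall 1.13 (0.89-1.44)                   1.61      0.990
#> 5       hybrid      30 prevalent 1.13 (0.72-1.79)                   2.50      0.990
#> 6       hybrid      30  incident 1.12 (0.85-1.48)                   1.75      0.990
```

The scenario has a null treatment effect with strong confounding: the same
covariates drive drug choice, switching and the outcome. The estimated
hazard ratios are compatible with 1 under both exposure-set definitions, and
the balance table shows what the matching achieved — standardized
differences of 0.18–0.39 before matching collapse to under 0.05 after:

```r
report$configs$hybrid_30d$balance[, c("covariate", "asd_unmatched", "asd_matched")]
#>   covariate asd_unmatched asd_matched
#> 1       age     0.3585132  0.02565734
#> 2      male     0.1841015  0.04858745
#> 3  comorbid     0.3936766  0.04476437
```

Each stage is also exposed on its own (`classify_new_users()`,
`build_episodes()`, `build_exposure_sets()`, `sample_within_sets()`,
`fit_tcps()`, `predict_tcps()`, `check_positivity()`,
`match_chronological()`, `build_followup()`, `fit_cox_robust()`,
`balance_table()`), so individual design decisions can be inspected or
replaced. `write_pnu_dataset()` / `read_pnu_dataset()` move the three
analysis tables through plain CSV, with the simulation ground truth
quarantined in a separate `truth.json` the pipeline never reads.

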