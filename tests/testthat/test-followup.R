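# minimal matched-pair fixture on a numeric day scale
fu_fixture <- function(events = data.frame(patient_id = integer(0),
                                           event_date = numeric(0),
                                           event_type = character(0)),
                       death = NA_real_, transfer = NA_real_,
                       study_end = 1000, comp_switch = NA_real_) {
  pairs <- data.frame(pair_id = 1L, set_id = 1L,
                      treated_patient_id = 1L, treated_index_date = 0,
                      treated_role = "incident_study",
                      comparator_patient_id = 2L, comparator_index_date = 0,
                      treated_score = 0.5, comparator_score = 0.5)
  episodes <- rbind(
    data.frame(patient_id = 1L, drug_class = "study", start_date = 0,
               supply_end_date = 28, episode_end_date = 58, n_rx = 1L),
    data.frame(patient_id = 2L, drug_class = "comparator", start_date = 0,
               supply_end_date = 28, episode_end_date = 58, n_rx = 1L))
  patients <- data.frame(patient_id = 1:2, death_date = c(death, NA),
                         transfer_date = c(transfer, NA))
  cohort <- data.frame(patient_id = 2L, role = "comparator",
                       entry_date = 0, index_date = NA_real_,
                       prior_comparator_rx = 0L, time_since_entry_days = 0L,
                       calendar_year = NA_integer_,
                       switch_date = comp_switch)
  build_followup(pairs, episodes, events, patients, cohort, study_end)
}

test_that("follow-up ends at the earliest censoring cause", {
  # nothing happens: discontinuation at episode end (day 58)
  fu <- fu_fixture()
  tr <- fu[fu$arm == "study", ]
  expect_equal(tr$t_stop, 58)
  expect_equal(tr$censor_reason, "discontinuation")
  expect_equal(tr$event, 0L)

  # outcome at day 30 beats the episode end
  fu <- fu_fixture(events = data.frame(patient_id = 1L, event_date = 30,
                                       event_type = "outcome"))
  tr <- fu[fu$arm == "study", ]
  expect_equal(tr$t_stop, 30)
  expect_equal(tr$event, 1L)
  expect_equal(tr$censor_reason, "outcome")

  # death at day 40 beats the episode end, and is not an event
  fu <- fu_fixture(death = 40)
  tr <- fu[fu$arm == "study", ]
  expect_equal(tr$t_stop, 40)
  expect_equal(tr$censor_reason, "death")
  expect_equal(tr$event, 0L)

  # cirrhosis-analogue censoring
  fu <- fu_fixture(events = data.frame(patient_id = 1L, event_date = 20,
                                       event_type = "cirrhosis"))
  expect_equal(fu$censor_reason[fu$arm == "study"], "cirrhosis")

  # administrative study end before the episode runs out
  fu <- fu_fixture(study_end = 10)
  expect_equal(unique(fu$t_stop), 10)
  expect_equal(unique(fu$censor_reason), "study_end")
})

test_that("a comparator's switch to the study drug censors as discontinuation", {
  fu <- fu_fixture(comp_switch = 21)
  cp <- fu[fu$arm == "comparator", ]
  expect_equal(cp$t_stop, 21)
  expect_equal(cp$censor_reason, "discontinuation")
  # the treated partner is unaffected
  expect_equal(fu$t_stop[fu$arm == "study"], 58)
})

test_that("an event on the index date keeps follow-up positive", {
  fu <- fu_fixture(events = data.frame(patient_id = 1L, event_date = 0,
                                       event_type = "outcome"))
  tr <- fu[fu$arm == "study", ]
  expect_equal(tr$t_stop, 0.5)
  expect_equal(tr$event, 1L)
})

test_that("an index date outside any episode is an upstream error", {
  pairs <- data.frame(pair_id = 1L, set_id = 1L,
                      treated_patient_id = 1L, treated_index_date = 500,
                      treated_role = "incident_study",
                      comparator_patient_id = 2L, comparator_index_date = 0,
                      treated_score = 0.5, comparator_score = 0.5)
  episodes <- data.frame(patient_id = 1:2,
                         drug_class = c("study", "comparator"),
                         start_date = 0, supply_end_date = 28,
                         episode_end_date = 58, n_rx = 1L)
  patients <- data.frame(patient_id = 1:2, death_date = NA_real_,
                         transfer_date = NA_real_)
  cohort <- data.frame(patient_id = 2L, role = "comparator",
                       entry_date = 0, switch_date = NA_real_)
  expect_error(build_followup(pairs, episodes,
                              data.frame(patient_id = integer(0),
                                         event_date = numeric(0),
                                         event_type = character(0)),
                              patients, cohort, 1000),
               "not inside any treatment episode")
})

test_that("exactly one censoring reason per record, events only for outcomes", {
  fx <- small_sim()
  rep <- run_pnu(fx$sim$patients, fx$sim$prescriptions, fx$sim$events,
                 window = fx$window, definitions = "hybrid", seed = 2)
  fu <- rep$configs$hybrid_30d$followup
  expect_true(all(fu$t_stop > 0))
  expect_true(all(fu$censor_reason %in%
                    c("outcome", "study_end", "death", "cirrhosis",
                      "transfer", "discontinuation")))
  expect_equal(fu$event == 1L, fu$censor_reason == "outcome")
  expect_equal(sum(table(fu$censor_reason)), nrow(fu))
  # two records per pair, one per arm
  expect_true(all(table(fu$pair_id) == 2L))
})

test_that("Cox estimates match a partial-likelihood grid search, score zero", {
  set.seed(55)
  n <- 20L
  x <- rep(0:1, each = n / 2)
  time <- round(rexp(n, 0.02 * exp(0.6 * x)), 3)
  status <- rbinom(n, 1L, 0.8)
  rec <- data.frame(patient_id = 1:n,
                    arm = ifelse(x == 1, "study", "comparator"),
                    pair_id = rep(1:(n / 2), 2), subgroup = "incident",
                    t_stop = time, event = status,
                    censor_reason = ifelse(status == 1, "outcome",
                                           "discontinuation"))
  est <- fit_cox_robust(rec)
  grid <- seq(-2, 2.5, by = 1e-4)
  ll <- vapply(grid, function(b) oracle_cox_loglik(b, time, status, x),
               numeric(1L))
  expect_equal(est$log_hr, grid[which.max(ll)], tolerance = 1e-3)
  g <- num_grad(function(b) oracle_cox_loglik(b, time, status, x),
                est$log_hr)
  expect_lt(abs(g), 1e-4)
})

test_that("symmetric event patterns give a near-zero log hazard ratio", {
  rec <- data.frame(patient_id = 1:40,
                    arm = rep(c("study", "comparator"), each = 20),
                    pair_id = rep(1:20, 2), subgroup = "incident",
                    t_stop = rep(c(5, 10, 15, 20), 10),
                    event = rep(c(1L, 0L), 20),
                    censor_reason = rep(c("outcome", "discontinuation"), 20))
  est <- fit_cox_robust(rec)
  expect_equal(est$log_hr, 0, tolerance = 1e-8)
  expect_true(est$finite)
  expect_gte(est$confidence_limit_ratio, 1)
  # the interval always contains the point estimate
  expect_true(est$ci95[1] <= est$hr && est$hr <= est$ci95[2])
})

test_that("an arm without events is flagged non-finite, not an error", {
  rec <- data.frame(patient_id = 1:10,
                    arm = rep(c("study", "comparator"), each = 5),
                    pair_id = rep(1:5, 2), subgroup = "prevalent",
                    t_stop = 1:10,
                    event = rep(c(1L, 0L), each = 5),
                    censor_reason = rep(c("outcome", "discontinuation"),
                                        each = 5))
  est <- fit_cox_robust(rec)
  expect_false(est$finite)
  expect_true(is.na(est$log_hr))
  # subgroup filtering selects records by the treated role's subgroup
  est2 <- fit_cox_robust(rec, subgroup = "incident")
  expect_equal(est2$n_records, 0L)
})

test_that("confidence limit ratios divide upper by lower bounds", {
  expect_equal(round(confidence_limit_ratio(c(0.73, 1.35)), 2), 1.85)
  expect_equal(round(confidence_limit_ratio(c(0.66, 2.55)), 2), 3.86)
  expect_equal(confidence_limit_ratio(c(0.8, 0.8)), 1)
  expect_error(confidence_limit_ratio(c(-1, 2)), "positive")
  expect_error(confidence_limit_ratio(c(2, 1)), "exceeds")
})
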