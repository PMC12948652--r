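#' Simulation configuration for the synthetic EHR generator
#'
#' Assembles and validates the parameters of the synthetic
#' electronic-health-record generator. The generator emulates the setting the
#' PNU design targets: staggered cohort entry over a multi-year window, a
#' newly introduced study drug whose uptake rises over calendar time,
#' covariate-driven switching from the comparator to the study drug, repeat
#' prescriptions with refill gaps, and an outcome following a
#' proportional-hazards process with known treatment and confounder effects.
#'
#' Covariate effects (`choice_log_or`, `switch_log_hazard$coefs`,
#' `confounder_log_hrs`) are named vectors whose names must match design
#' columns derived from `covariates`: a continuous or binary covariate
#' contributes a column under its own name; a categorical covariate named
#' `v` with levels `a, b, c` contributes dummy columns `v_b`, `v_c`
#' (first level is the reference). Effects apply to mean-centred columns so
#' that `uptake_curve`, `switch_log_hazard$intercept` and
#' `outcome_baseline_rate` keep their interpretation for an average patient.
#'
#' @param n_patients positive integer, number of patients to simulate.
#' @param window_start,window_end calendar dates bounding cohort entry
#'   (first prescriptions are drawn uniformly over this window).
#' @param covariates named list of covariate specifications; each element is
#'   `list(kind = "continuous", mean =, sd =)`,
#'   `list(kind = "binary", p =)`, or
#'   `list(kind = "categorical", levels =, probs =)`.
#' @param uptake_curve named numeric vector, one probability per calendar
#'   year in the window: the probability that an average patient's first
#'   initiation is the study drug rather than the comparator.
#' @param choice_log_or named numeric vector of covariate log odds-ratios on
#'   the study-vs-comparator choice at first initiation (may be empty).
#' @param switch_log_hazard `list(intercept =, coefs =)`: log hazard per day
#'   of switching from comparator to study drug; `intercept = -Inf` disables
#'   switching.
#' @param rx_duration_days positive integer, days of supply per prescription.
#' @param refill_gap_mean nonnegative mean (Poisson) of the gap in days
#'   between supply end and the next issue.
#' @param stop_prob probability in \[0,1\] that the patient discontinues
#'   after any given prescription's supply ends.
#' @param true_log_hr treatment effect: log hazard ratio of the outcome for
#'   current-or-former study-drug initiators versus never-initiators.
#' @param outcome_baseline_rate outcome events per person-day for an average
#'   never-treated patient.
#' @param confounder_log_hrs named numeric vector of covariate log hazard
#'   ratios on the outcome (may be empty).
#' @param censor_rates named numeric vector with elements `death`,
#'   `transfer`, `cirrhosis`: independent exponential rates per person-day.
#' @param short_history_frac fraction of patients given less than a year of
#'   registered history before their first prescription, so that washout
#'   exclusion is exercised.
#' @param seed integer RNG seed; the generator is bit-reproducible given the
#'   seed.
#'
#' @return An object of class `pnu_sim_config` (a validated list).
#' @seealso [generate_population()], [confounded_scenario()]
#' @export
#' @examples
#' cfg <- sim_config(n_patients = 100, seed = 1)
#' cfg$uptake_curve
sim_config <- function(n_patients,
                       window_start = as.Date("2000-01-01"),
                       window_end = as.Date("2004-12-31"),
                       covariates = default_covariates(),
                       uptake_curve = c(`2000` = 0.05, `2001` = 0.12,
                                        `2002` = 0.20, `2003` = 0.27,
                                        `2004` = 0.35),
                       choice_log_or = numeric(0),
                       switch_log_hazard = list(intercept = log(2e-4),
                                                coefs = numeric(0)),
                       rx_duration_days = 28L,
                       refill_gap_mean = 4,
                       stop_prob = 0.15,
                       true_log_hr = 0,
                       outcome_baseline_rate = 5e-4,
                       confounder_log_hrs = numeric(0),
                       censor_rates = c(death = 5e-5, transfer = 1e-4,
                                        cirrhosis = 5e-6),
                       short_history_frac = 0.05,
                       seed = 1L) {
  window_start <- as.Date(window_start)
  window_end <- as.Date(window_end)
  if (length(n_patients) != 1L || is.na(n_patients) || n_patients < 1)
    stop("n_patients must be a positive integer")
  if (window_start >= window_end)
    stop("degenerate window: start must precede end")
  years <- format(seq(window_start, window_end, by = "year"), "%Y")
  if (!all(years %in% names(uptake_curve)))
    stop("uptake_curve must name every calendar year in the window")
  if (any(uptake_curve < 0 | uptake_curve > 1))
    stop("uptake probabilities must lie in [0, 1]")
  if (rx_duration_days < 1) stop("rx_duration_days must be positive")
  if (stop_prob < 0 || stop_prob > 1) stop("stop_prob must lie in [0, 1]")
  if (outcome_baseline_rate < 0 || refill_gap_mean < 0 ||
      any(censor_rates < 0))
    stop("rates must be nonnegative")
  if (!all(c("death", "transfer", "cirrhosis") %in% names(censor_rates)))
    stop("censor_rates must name death, transfer and cirrhosis")

  cols <- design_colnames(covariates)
  for (v in list(choice_log_or, switch_log_hazard$coefs, confounder_log_hrs)) {
    if (length(v) && !all(names(v) %in% cols))
      stop("effect names must match design columns: ",
           paste(setdiff(names(v), cols), collapse = ", "))
  }

  structure(list(
    n_patients = as.integer(n_patients),
    window_start = window_start, window_end = window_end,
    covariates = covariates, uptake_curve = uptake_curve,
    choice_log_or = choice_log_or, switch_log_hazard = switch_log_hazard,
    rx_duration_days = as.integer(rx_duration_days),
    refill_gap_mean = refill_gap_mean, stop_prob = stop_prob,
    true_log_hr = true_log_hr,
    outcome_baseline_rate = outcome_baseline_rate,
    confounder_log_hrs = confounder_log_hrs, censor_rates = censor_rates,
    short_history_frac = short_history_frac, seed = as.integer(seed)
  ), class = "pnu_sim_config")
}

#' Default covariate specification
#'
#' Age (years), sex and one chronic-comorbidity indicator — a minimal version
#' of the covariate block a GI-bleed propensity model would carry.
#'
#' @return Named list of covariate specifications for [sim_config()].
#' @export
default_covariates <- function() {
  list(
    age = list(kind = "continuous", mean = 65, sd = 12),
    male = list(kind = "binary", p = 0.40),
    comorbid = list(kind = "binary", p = 0.30)
  )
}

# design column names implied by a covariate spec (categoricals expand to
# dummies against the first level)
design_colnames <- function(covariates) {
  unlist(lapply(names(covariates), function(nm) {
    sp <- covariates[[nm]]
    if (sp$kind == "categorical") paste0(nm, "_", sp$levels[-1L]) else nm
  }), use.names = FALSE)
}

#' Ready-made confounded simulation scenario
#'
#' Builds a [sim_config()] in which the same covariates (age, sex,
#' comorbidity) drive treatment choice, comparator-to-study switching and the
#' outcome hazard, with all covariate coefficients scaled by `strength`.
#' `strength = 0` gives a randomized-treatment configuration (no covariate
#' enters any treatment or outcome model); `strength = 1` produces marked
#' imbalance (standardized differences well above 0.1) between unmatched
#' arms, the situation TCPS matching is designed to repair.
#'
#' @param strength nonnegative scalar multiplying every covariate
#'   coefficient in the choice, switch and outcome models.
#' @param seed integer RNG seed stored in the config.
#' @param n_patients cohort size (default 10000).
#' @param true_log_hr treatment effect on the outcome (default 0, a null
#'   scenario).
#' @return A `pnu_sim_config`.
#' @export
#' @examples
#' cfg <- confounded_scenario(strength = 1, seed = 7, n_patients = 2000)
confounded_scenario <- function(strength, seed, n_patients = 10000L,
                                true_log_hr = 0) {
  if (length(strength) != 1L || is.na(strength) || strength < 0)
    stop("strength must be a nonnegative scalar")
  choice <- strength * c(age = 0.03, male = 0.5, comorbid = 0.8)
  switchc <- strength * c(age = 0.03, male = 0.5, comorbid = 0.8)
  outcome <- strength * c(age = 0.02, male = 0.4, comorbid = 0.7)
  keep <- function(v) v[v != 0]
  sim_config(
    n_patients = n_patients,
    choice_log_or = keep(choice),
    switch_log_hazard = list(intercept = log(8e-4), coefs = keep(switchc)),
    true_log_hr = true_log_hr,
    confounder_log_hrs = keep(outcome),
    seed = seed
  )
}

#' @export
print.pnu_sim_config <- function(x, ...) {
  cat("<pnu_sim_config>\n")
  cat("  patients:", x$n_patients, " window:",
      format(x$window_start), "..", format(x$window_end), "\n")
  cat("  covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  cat("  true log HR:", x$true_log_hr,
      " baseline outcome rate:", x$outcome_baseline_rate, "/day\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
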