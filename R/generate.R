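#' Generate a synthetic longitudinal EHR dataset
#'
#' Simulates patients, repeat prescriptions and outcome/censoring events with
#' the statistical structure the PNU design assumes. Each patient enters at a
#' first prescription drawn uniformly over the study window; the first drug is
#' study or comparator with a probability set by the calendar-year uptake
#' curve shifted by covariate effects; comparator users carry an exponential
#' switch clock (covariate-dependent rate) and switch to the study drug at the
#' first issue after it fires; prescriptions repeat with Poisson refill gaps
#' until discontinuation, death, transfer, outcome or the window end. Outcome
#' times follow a piecewise-exponential proportional-hazards model whose
#' hazard is multiplied by `exp(true_log_hr)` from the moment of study-drug
#' initiation onward (treatment is time-fixed from initiation, so the
#' marginal hazard ratio in an as-treated analysis equals the configured
#' value).
#'
#' The ground truth (latent switch and outcome times, true effect) is
#' returned in a separate `truth` component that the analysis pipeline never
#' reads.
#'
#' @param config a [sim_config()] object.
#' @return An object of class `pnu_sim`: a list with data.frames `patients`
#'   (id, registration/death/transfer dates, covariates), `prescriptions`
#'   (id, drug_class, issue_date, supply_days), `events` (id, event_date,
#'   event_type in outcome/cirrhosis), a `truth` list, and the `config`.
#' @export
#' @examples
#' sim <- generate_population(sim_config(n_patients = 200, seed = 42))
#' table(sim$prescriptions$drug_class)
generate_population <- function(config) {
  if (!inherits(config, "pnu_sim_config"))
    stop("config must be built with sim_config()")
  set.seed(config$seed)
  n <- config$n_patients
  horizon_all <- as.integer(config$window_end - config$window_start)

  cov <- draw_covariates(config$covariates, n)
  xc <- cov$design # centred design matrix

  # staggered entry: first prescription uniform over the window
  first_rx <- config$window_start +
    floor(runif(n, 0, horizon_all + 1))
  horizon <- as.integer(config$window_end - first_rx)

  # registered history: mostly > 1 year, a small fraction too short
  hist_days <- 365 + round(rexp(n, 1 / 900))
  short <- runif(n) < config$short_history_frac
  hist_days[short] <- round(runif(sum(short), 30, 300))
  registration_date <- first_rx - hist_days

  # first drug: calendar-year uptake shifted by covariates on the logit scale
  yr <- format(first_rx, "%Y")
  eta_choice <- qlogis(config$uptake_curve[yr]) +
    lin_pred(xc, config$choice_log_or)
  first_drug_study <- runif(n) < plogis(eta_choice)

  # latent clocks, in days after first prescription
  rate_sw <- exp(config$switch_log_hazard$intercept +
                   lin_pred(xc, config$switch_log_hazard$coefs))
  t_switch <- exp_time(n, rate_sw)
  t_switch[first_drug_study] <- 0
  t_death <- exp_time(n, config$censor_rates[["death"]])
  t_transfer <- exp_time(n, config$censor_rates[["transfer"]])
  t_cirr <- exp_time(n, config$censor_rates[["cirrhosis"]])

  rx <- simulate_prescriptions(config, first_drug_study, t_switch,
                               pmin(t_death, t_transfer), horizon)

  # study-drug initiation actually realised (an issue date)
  s_real <- ifelse(first_drug_study, 0, rx$switched_day)

  # piecewise-exponential outcome: hazard jumps by exp(true_log_hr) at s_real
  r0 <- config$outcome_baseline_rate *
    exp(lin_pred(xc, config$confounder_log_hrs))
  e0 <- exp_time(n, r0)
  t_out <- ifelse(e0 < s_real, e0,
                  s_real + exp_time(n, r0 * exp(config$true_log_hr)))
  out_day <- ceiling(t_out)

  # prescriptions stop at the outcome (no issues after death/transfer/outcome)
  issues <- rx$issues[rx$issues$day <= pmin(out_day, Inf)[rx$issues$id], ]

  prescriptions <- data.frame(
    patient_id = issues$id,
    drug_class = ifelse(issues$study, "study", "comparator"),
    issue_date = first_rx[issues$id] + issues$day,
    supply_days = config$rx_duration_days,
    stringsAsFactors = FALSE
  )
  prescriptions <- prescriptions[order(prescriptions$patient_id,
                                       prescriptions$issue_date), ]
  rownames(prescriptions) <- NULL

  patients <- data.frame(
    patient_id = seq_len(n),
    registration_date = registration_date,
    death_date = observed_date(first_rx, t_death, config$window_end),
    transfer_date = observed_date(first_rx, t_transfer, config$window_end),
    stringsAsFactors = FALSE
  )
  patients <- cbind(patients, cov$raw)

  ev_out <- which(out_day <= horizon & t_out < t_death & t_out < t_transfer)
  ev_cir <- which(ceiling(t_cirr) <= horizon & t_cirr < t_death &
                    t_cirr < t_transfer)
  events <- rbind(
    data.frame(patient_id = ev_out, event_date = first_rx[ev_out] +
                 out_day[ev_out],
               event_type = rep_len("outcome", length(ev_out))),
    data.frame(patient_id = ev_cir, event_date = first_rx[ev_cir] +
                 ceiling(t_cirr)[ev_cir],
               event_type = rep_len("cirrhosis", length(ev_cir)))
  )
  events <- events[order(events$patient_id, events$event_date), ]
  rownames(events) <- NULL

  truth <- list(
    true_log_hr = config$true_log_hr,
    latent = data.frame(
      patient_id = seq_len(n),
      first_rx_date = first_rx,
      first_drug = ifelse(first_drug_study, "study", "comparator"),
      latent_switch_day = t_switch,
      realized_switch_day = rx$switched_day,
      latent_outcome_day = t_out
    )
  )

  structure(list(patients = patients, prescriptions = prescriptions,
                 events = events, truth = truth, config = config),
            class = "pnu_sim")
}

# covariate draws: raw values plus a mean-centred numeric design matrix
draw_covariates <- function(covariates, n) {
  raw <- list()
  design <- list()
  for (nm in names(covariates)) {
    sp <- covariates[[nm]]
    if (sp$kind == "continuous") {
      v <- rnorm(n, sp$mean, sp$sd)
      raw[[nm]] <- v
      design[[nm]] <- v - sp$mean
    } else if (sp$kind == "binary") {
      v <- rbinom(n, 1L, sp$p)
      raw[[nm]] <- v
      design[[nm]] <- v - sp$p
    } else if (sp$kind == "categorical") {
      v <- sample(sp$levels, n, replace = TRUE, prob = sp$probs)
      raw[[nm]] <- v
      for (j in seq_along(sp$levels)[-1L]) {
        design[[paste0(nm, "_", sp$levels[j])]] <-
          as.numeric(v == sp$levels[j]) - sp$probs[j]
      }
    } else stop("unknown covariate kind: ", sp$kind)
  }
  list(raw = as.data.frame(raw, stringsAsFactors = FALSE),
       design = do.call(cbind, design))
}

lin_pred <- function(design, coefs) {
  if (!length(coefs)) return(rep(0, nrow(design)))
  drop(design[, names(coefs), drop = FALSE] %*% coefs)
}

# exponential waiting time; rate 0 (or -Inf log-rate) means "never"
exp_time <- function(n, rate) {
  rate <- rep_len(rate, n)
  t <- rep(Inf, n)
  pos <- rate > 0
  t[pos] <- rexp(sum(pos)) / rate[pos]
  t
}

observed_date <- function(origin, t_days, end) {
  d <- origin + ceiling(t_days)
  d[!is.finite(t_days) | d > end] <- NA
  d
}

# vectorised repeat-prescription process; returns the issue log and the day
# (after first prescription) at which each comparator initiator switched
simulate_prescriptions <- function(config, on_study, t_switch, t_stop_hard,
                                   horizon) {
  n <- length(on_study)
  next_day <- rep(0L, n)
  active <- rep(TRUE, n)
  switched_day <- ifelse(on_study, 0, Inf)
  acc_id <- list(); acc_day <- list(); acc_study <- list(); it <- 0L
  while (any(active)) {
    it <- it + 1L
    idx <- which(active)
    day <- next_day[idx]
    ok <- day <= horizon[idx] & day < t_stop_hard[idx]
    active[idx[!ok]] <- FALSE
    idx <- idx[ok]; day <- day[ok]
    if (!length(idx)) break
    sw <- !on_study[idx] & day >= t_switch[idx]
    on_study[idx[sw]] <- TRUE
    switched_day[idx[sw]] <- day[sw]
    acc_id[[it]] <- idx
    acc_day[[it]] <- day
    acc_study[[it]] <- on_study[idx]
    stop_now <- runif(length(idx)) < config$stop_prob
    active[idx[stop_now]] <- FALSE
    cont <- !stop_now
    next_day[idx[cont]] <- day[cont] + config$rx_duration_days +
      rpois(sum(cont), config$refill_gap_mean)
  }
  list(issues = data.frame(id = unlist(acc_id), day = unlist(acc_day),
                           study = unlist(acc_study)),
       switched_day = switched_day)
}

#' @export
print.pnu_sim <- function(x, ...) {
  cat("<pnu_sim>", nrow(x$patients), "patients,",
      nrow(x$prescriptions), "prescriptions,",
      nrow(x$events), "events\n")
  cat("  window:", format(x$config$window_start), "..",
      format(x$config$window_end),
      " true log HR:", x$truth$true_log_hr, "\n")
  invisible(x)
}

#' Write / read a synthetic dataset as delimited text
#'
#' `write_pnu_dataset()` writes `patients.csv`, `prescriptions.csv` and
#' `events.csv` (ISO-8601 dates) plus `truth.json` to a directory; the truth
#' file is separate so the analysis tables can be handed to the pipeline
#' without leaking ground truth. `read_pnu_dataset()` reads the three
#' analysis tables back (never the truth).
#'
#' @param sim a `pnu_sim` object.
#' @param dir directory to write to (created if needed).
#' @return `write_pnu_dataset()` returns `dir` invisibly;
#'   `read_pnu_dataset()` returns a list with `patients`, `prescriptions`
#'   and `events` data.frames.
#' @export
write_pnu_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "pnu_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(sim$patients, file.path(dir, "patients.csv"))
  data.table::fwrite(sim$prescriptions, file.path(dir, "prescriptions.csv"))
  data.table::fwrite(sim$events, file.path(dir, "events.csv"))
  jsonlite::write_json(
    list(true_log_hr = sim$truth$true_log_hr,
         latent = sim$truth$latent),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(dir)
}

#' @rdname write_pnu_dataset
#' @export
read_pnu_dataset <- function(dir) {
  rd <- function(f) {
    x <- as.data.frame(data.table::fread(file.path(dir, f)))
    for (col in names(x))
      if (inherits(x[[col]], "IDate")) x[[col]] <- as.Date(x[[col]])
    x
  }
  list(patients = rd("patients.csv"),
       prescriptions = rd("prescriptions.csv"),
       events = rd("events.csv"))
}
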