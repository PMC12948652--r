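#' As-treated follow-up for the matched cohort
#'
#' Builds one survival record per matched person. Time zero is the person's
#' index date (initiation date for study-drug users, the matched candidate
#' prescription date for comparators). Follow-up ends at the earliest of:
#' outcome occurrence, study end date, death, the cirrhosis-analogue
#' censoring event, transfer out of practice, or treatment discontinuation
#' (the end of the continuous treatment episode containing the index date; a
#' comparator's switch to the study drug also counts as discontinuation).
#' Exactly one censoring reason is recorded per record, with the outcome
#' taking precedence on ties, and `event = 1` exactly when the reason is
#' the outcome. Records whose earliest endpoint coincides with the index
#' date are given half a day of follow-up so that survival times stay
#' positive at day granularity.
#'
#' @param pairs matched pairs from [match_chronological()].
#' @param episodes treatment episodes from [build_episodes()].
#' @param events event table (`patient_id`, `event_date`, `event_type` with
#'   types `outcome` and `cirrhosis`).
#' @param patients patient table (`death_date`, `transfer_date`).
#' @param cohort base cohort from [classify_new_users()] (supplies
#'   comparator switch dates).
#' @param study_end administrative end of follow-up.
#' @return data.frame of `FollowUpRecord`s: `patient_id`, `arm`, `pair_id`,
#'   `subgroup` (incident/prevalent), `t_stop` (days), `event`,
#'   `censor_reason`.
#' @export
build_followup <- function(pairs, episodes, events, patients, cohort,
                           study_end) {
  if (!nrow(pairs))
    return(data.frame(patient_id = integer(0), arm = character(0),
                      pair_id = integer(0), subgroup = character(0),
                      t_stop = numeric(0), event = integer(0),
                      censor_reason = character(0)))
  sub <- ifelse(pairs$treated_role == "prevalent_study", "prevalent",
                "incident")
  persons <- rbind(
    data.frame(patient_id = pairs$treated_patient_id, arm = "study",
               pair_id = pairs$pair_id, subgroup = sub,
               index_date = pairs$treated_index_date),
    data.frame(patient_id = pairs$comparator_patient_id, arm = "comparator",
               pair_id = pairs$pair_id, subgroup = sub,
               index_date = pairs$comparator_index_date)
  )
  pd <- as.data.table(persons)
  pd[, drug_class := fifelse(arm == "study", "study", "comparator")]

  ep <- as.data.table(episodes)
  hit <- ep[pd, on = .(patient_id, drug_class, start_date <= index_date,
                       episode_end_date > index_date),
            .(patient_id = i.patient_id, arm = i.arm, pair_id = i.pair_id,
              subgroup = i.subgroup, index_date = i.index_date,
              episode_end = x.episode_end_date)]
  if (anyNA(hit$episode_end))
    stop("index date not inside any treatment episode for ",
         sum(is.na(hit$episode_end)), " matched person(s)")
  # an index date could in principle sit in two episodes only if episodes
  # overlapped, which build_episodes() precludes; keep the first defensively
  hit <- hit[, .SD[1L], by = .(pair_id, arm, patient_id)]

  ev <- as.data.table(events)
  first_ev <- function(type) {
    ev[event_type == type][
      hit, on = .(patient_id, event_date >= index_date),
      .(d = min(x.event_date)), by = .EACHI][, d]
  }
  out_ev <- first_ev("outcome")
  cir_ev <- first_ev("cirrhosis")

  pat <- as.data.table(patients)[, .(patient_id, death_date, transfer_date)]
  hit[pat, on = .(patient_id),
      `:=`(death_date = i.death_date, transfer_date = i.transfer_date)]

  # comparator follow-up also ends at that person's switch to the study drug
  sw <- as.data.table(cohort)[role == "comparator",
                              .(patient_id, switch_date)]
  hit[sw, on = .(patient_id), switch_date := i.switch_date]
  hit[arm == "study", switch_date := NA]

  disc <- pmin(hit$episode_end, hit$switch_date, na.rm = TRUE)
  days <- function(d) as.numeric(d) - as.numeric(hit$index_date)
  end_num <- if (inherits(hit$index_date, "Date"))
    as.numeric(as.Date(study_end)) else as.numeric(study_end)
  cand <- cbind(
    outcome = days(out_ev),
    study_end = end_num - as.numeric(hit$index_date),
    death = days(hit$death_date),
    cirrhosis = days(cir_ev),
    transfer = days(hit$transfer_date),
    discontinuation = days(disc)
  )
  cand[is.na(cand)] <- Inf
  # outcome sits first so it wins ties among simultaneous causes
  which_min <- max.col(-cand, ties.method = "first")
  t_stop <- cand[cbind(seq_len(nrow(cand)), which_min)]
  reason <- colnames(cand)[which_min]
  t_stop[t_stop <= 0] <- 0.5

  out <- data.frame(
    patient_id = hit$patient_id, arm = hit$arm, pair_id = hit$pair_id,
    subgroup = hit$subgroup, t_stop = t_stop,
    event = as.integer(reason == "outcome"), censor_reason = reason
  )
  out[order(out$pair_id, out$arm, decreasing = c(FALSE, TRUE),
            method = "radix"), , drop = FALSE]
}

#' Cox hazard-ratio estimate with robust standard errors
#'
#' Fits an unstratified Cox proportional-hazards model of the outcome on the
#' treatment indicator in the matched as-treated cohort (Breslow tie
#' handling), with a robust sandwich variance — clustered on the individual
#' by default, or on the matched pair with `cluster_by_pair = TRUE`.
#' Subgroup estimates (`prevalent`, `incident`) refit the model on that
#' subgroup's records. When either arm has no events the estimate is
#' returned flagged non-finite rather than failing.
#'
#' @param records follow-up records from [build_followup()].
#' @param subgroup one of "overall", "prevalent", "incident".
#' @param cluster_by_pair cluster the sandwich variance on matched pair
#'   (default FALSE: individual-level robust variance).
#' @return Object of class `pnu_effect`: `subgroup`, `log_hr`, `hr`,
#'   `robust_se`, `ci95` (low, high), `confidence_limit_ratio`,
#'   `n_events_study`, `n_events_comparator`, `n_records`, `finite`.
#' @export
fit_cox_robust <- function(records,
                           subgroup = c("overall", "prevalent", "incident"),
                           cluster_by_pair = FALSE) {
  subgroup <- match.arg(subgroup)
  rec <- if (subgroup == "overall") records
         else records[records$subgroup == subgroup, , drop = FALSE]
  n_ev <- c(study = sum(rec$event[rec$arm == "study"]),
            comparator = sum(rec$event[rec$arm == "comparator"]))
  base <- list(subgroup = subgroup, n_events_study = unname(n_ev["study"]),
               n_events_comparator = unname(n_ev["comparator"]),
               n_records = nrow(rec))
  if (any(n_ev == 0L) || !nrow(rec)) {
    return(structure(c(base, list(log_hr = NA_real_, hr = NA_real_,
                                  robust_se = NA_real_,
                                  ci95 = c(NA_real_, NA_real_),
                                  confidence_limit_ratio = NA_real_,
                                  finite = FALSE)),
                     class = "pnu_effect"))
  }
  rec$treated01 <- as.integer(rec$arm == "study")
  fit <- if (cluster_by_pair)
    survival::coxph(survival::Surv(t_stop, event) ~ treated01 +
                      survival::cluster(pair_id),
                    data = rec, ties = "breslow")
  else
    survival::coxph(survival::Surv(t_stop, event) ~ treated01,
                    data = rec, ties = "breslow", robust = TRUE)
  log_hr <- unname(fit$coefficients[1L])
  se <- sqrt(diag(fit$var))[1L] # robust variance when robust/cluster is set
  ci <- exp(log_hr + c(-1, 1) * 1.96 * se)
  structure(c(base, list(log_hr = log_hr, hr = exp(log_hr), robust_se = se,
                         ci95 = ci,
                         confidence_limit_ratio = ci[2L] / ci[1L],
                         finite = is.finite(log_hr) && is.finite(se))),
            class = "pnu_effect")
}

#' @export
print.pnu_effect <- function(x, ...) {
  cat(sprintf("<pnu_effect> %s: HR %.2f (95%% CI %.2f-%.2f), CLR %.2f\n",
              x$subgroup, x$hr, x$ci95[1L], x$ci95[2L],
              x$confidence_limit_ratio))
  cat(sprintf("  events: %d study vs %d comparator, %d records\n",
              x$n_events_study, x$n_events_comparator, x$n_records))
  invisible(x)
}

#' Confidence limit ratio
#'
#' Ratio of the upper to the lower bound of a 95% confidence interval for a
#' hazard ratio; a scale-free precision summary (always >= 1).
#'
#' @param ci95 numeric length-2 vector (low, high), both positive.
#' @return The ratio high/low.
#' @export
#' @examples
#' confidence_limit_ratio(c(0.73, 1.35)) # 1.85 to 2 d.p.
confidence_limit_ratio <- function(ci95) {
  if (length(ci95) != 2L || any(!is.finite(ci95)))
    stop("ci95 must be two finite numbers")
  if (ci95[1L] <= 0) stop("lower confidence limit must be positive")
  if (ci95[1L] > ci95[2L]) stop("lower limit exceeds upper limit")
  unname(ci95[2L] / ci95[1L])
}
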