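#' Build continuous treatment episodes from prescriptions
#'
#' Merges successive prescriptions of the same patient and drug class into
#' continuous treatment periods: a period runs from the first issue date to
#' the latest supply end among its prescriptions, plus a grace period. With
#' the default `bridge = "grace"`, a refill counts as a continuation when it
#' is issued no later than the current supply end plus `grace_days` (the same
#' gap after which as-treated follow-up would declare discontinuation);
#' `bridge = "strict"` requires true supply overlap.
#'
#' Date arithmetic treats supply intervals as half-open `[issue, issue +
#' supply_days)`, so `supply_end_date` is the first uncovered day and
#' `episode_end_date = supply_end_date + grace_days` is the discontinuation
#' date used for censoring.
#'
#' @param prescriptions data.frame with columns `patient_id`, `drug_class`,
#'   `issue_date` (Date or integer day), `supply_days` (>= 1).
#' @param grace_days nonnegative integer appended to the final supply end
#'   (default 30).
#' @param bridge `"grace"` (default) or `"strict"`: whether a gap bridged by
#'   the grace period keeps the episode alive.
#' @return data.frame with one row per episode: `patient_id`, `drug_class`,
#'   `start_date`, `supply_end_date`, `episode_end_date`, `n_rx`.
#' @export
#' @examples
#' rx <- data.frame(patient_id = 1, drug_class = "comparator",
#'                  issue_date = c(0, 50), supply_days = 28)
#' build_episodes(rx, grace_days = 30) # one episode ending day 108
build_episodes <- function(prescriptions, grace_days = 30L,
                           bridge = c("grace", "strict")) {
  bridge <- match.arg(bridge)
  if (grace_days < 0) stop("grace_days must be nonnegative")
  if (any(prescriptions$supply_days < 1)) stop("supply_days must be >= 1")
  if (!nrow(prescriptions)) {
    return(data.frame(patient_id = prescriptions$patient_id,
                      drug_class = character(0), start_date = numeric(0),
                      supply_end_date = numeric(0),
                      episode_end_date = numeric(0), n_rx = integer(0)))
  }
  dt <- as.data.table(prescriptions)[
    , .(patient_id, drug_class, issue_date, supply_days)]
  setorder(dt, patient_id, drug_class, issue_date)
  bridge_gap <- if (bridge == "grace") grace_days else 0L
  dt[, supply_end := issue_date + supply_days]
  dt[, episode_id := {
    run_end <- cummax(as.numeric(supply_end))
    new_ep <- c(TRUE,
                as.numeric(issue_date[-1L]) > run_end[-.N] + bridge_gap)
    cumsum(new_ep)
  }, by = .(patient_id, drug_class)]
  ep <- dt[, .(start_date = min(issue_date),
               supply_end_date = max(supply_end),
               n_rx = .N),
           by = .(patient_id, drug_class, episode_id)]
  ep[, episode_end_date := supply_end_date + grace_days]
  setorder(ep, patient_id, drug_class, start_date)
  out <- as.data.frame(ep[, .(patient_id, drug_class, start_date,
                              supply_end_date, episode_end_date, n_rx)])
  out
}

#' Count prior comparator prescriptions
#'
#' Number of comparator-class prescriptions of one patient issued strictly
#' before a reference date. The strict inequality makes the index
#' prescription itself the (k+1)-th: a study-drug user with k prior
#' comparator prescriptions is compared with comparator prescriptions that
#' are themselves the (k+1)-th issue.
#'
#' @param prescriptions prescription data.frame (`patient_id`, `drug_class`,
#'   `issue_date`).
#' @param patient_id the patient.
#' @param as_of reference date.
#' @return Nonnegative integer count.
#' @export
prior_rx_count <- function(prescriptions, patient_id, as_of) {
  sum(prescriptions$patient_id == patient_id &
        prescriptions$drug_class == "comparator" &
        prescriptions$issue_date < as_of)
}

#' Assemble the base cohort of new users and switchers
#'
#' A patient enters the base cohort at their first prescription of either
#' drug class inside the study window, provided (i) no prescription of either
#' class in the `washout_days` before it and (ii) at least `washout_days` of
#' registered history. The entering prescription's class assigns the role:
#' study drug gives an `incident_study` membership (index date = entry date);
#' comparator gives a `comparator` membership, and if the patient later
#' receives a first study-drug prescription inside the window they
#' additionally contribute a `prevalent_study` (switcher) membership indexed
#' at that first study-drug date, with the number of comparator prescriptions
#' issued strictly before it.
#'
#' Patients with a missing registration date, a washout violation, or
#' historical comparator use predating a study-drug entry prescription are
#' excluded; the exclusions with reasons are attached as
#' `attr(, "exclusions")`.
#'
#' @param patients patient table with `patient_id`, `registration_date`.
#' @param prescriptions prescription table (`patient_id`, `drug_class`,
#'   `issue_date`, `supply_days`).
#' @param window length-2 vector (start, end) of cohort-entry dates.
#' @param washout_days required drug-free, registered history before entry
#'   (default 365).
#' @return data.frame with one row per membership: `patient_id`, `role`
#'   (incident_study / prevalent_study / comparator), `entry_date`,
#'   `index_date` (study roles; NA for comparator), `prior_comparator_rx`,
#'   `time_since_entry_days`, `calendar_year`, `switch_date` (first
#'   study-drug date for comparator patients who switch, else NA).
#' @export
classify_new_users <- function(patients, prescriptions, window,
                               washout_days = 365L) {
  window <- as_window(window)
  rx <- as.data.table(prescriptions)
  if (nrow(rx) &&
      (min(rx$issue_date) > window[2L] || max(rx$issue_date) < window[1L]))
    warning("study window lies outside the prescription date range")
  setorder(rx, patient_id, issue_date)

  pat <- as.data.table(patients)[, .(patient_id, registration_date)]
  excl <- list()

  no_reg <- pat[is.na(registration_date), patient_id]
  if (length(no_reg))
    excl$missing_registration <- no_reg

  # first in-window prescription per patient = candidate entry
  firsts <- rx[issue_date >= window[1L] & issue_date <= window[2L],
               .SD[1L], by = patient_id]
  firsts <- merge(firsts, pat, by = "patient_id")
  firsts <- firsts[!patient_id %in% no_reg]

  # washout: no prescription of either class in the washout before entry,
  # and registered history covering the washout
  pre <- rx[firsts, on = .(patient_id),
            .(patient_id, issue_date = x.issue_date,
              drug_class = x.drug_class, entry = i.issue_date)]
  viol <- unique(pre[issue_date < entry &
                       issue_date >= entry - washout_days, patient_id])
  short <- firsts[registration_date > issue_date - washout_days, patient_id]
  excl$washout_violation <- viol
  excl$short_history <- setdiff(short, viol)
  firsts <- firsts[!patient_id %in% c(viol, short)]

  # historical comparator use before a study-drug entry prescription:
  # neither an incident new user nor an in-cohort switcher
  prior_comp <- pre[issue_date < entry & drug_class == "comparator",
                    .N, by = patient_id]
  hist_sw <- firsts[drug_class == "study" &
                      patient_id %in% prior_comp$patient_id, patient_id]
  excl$historical_switcher <- hist_sw
  firsts <- firsts[!patient_id %in% hist_sw]

  # first study-drug prescription in window, for switch detection
  rx_study <- rx[drug_class == "study" & issue_date >= window[1L] &
                   issue_date <= window[2L]]
  first_study <- if (nrow(rx_study))
    rx_study[, .(first_study = min(issue_date)), by = patient_id]
  else data.table(patient_id = rx$patient_id[0L],
                  first_study = rx$issue_date[0L])

  out <- list()
  inc <- firsts[drug_class == "study"]
  if (nrow(inc))
    out$incident <- data.table(
      patient_id = inc$patient_id, role = "incident_study",
      entry_date = inc$issue_date, index_date = inc$issue_date,
      prior_comparator_rx = 0L, time_since_entry_days = 0L,
      calendar_year = year_of(inc$issue_date), switch_date = na_like(inc$issue_date))

  comp <- firsts[drug_class == "comparator"]
  if (nrow(comp)) {
    comp <- merge(comp, first_study, by = "patient_id", all.x = TRUE)
    out$comparator <- data.table(
      patient_id = comp$patient_id, role = "comparator",
      entry_date = comp$issue_date, index_date = na_like(comp$issue_date),
      prior_comparator_rx = 0L, time_since_entry_days = 0L,
      calendar_year = NA_integer_, switch_date = comp$first_study)

    sw <- comp[!is.na(first_study) & first_study > issue_date]
    if (nrow(sw)) {
      nprior <- rx[drug_class == "comparator"][
        sw, on = .(patient_id, issue_date < first_study), .N,
        by = .EACHI][, N]
      out$prevalent <- data.table(
        patient_id = sw$patient_id, role = "prevalent_study",
        entry_date = sw$issue_date, index_date = sw$first_study,
        prior_comparator_rx = as.integer(nprior),
        time_since_entry_days = as.integer(sw$first_study - sw$issue_date),
        calendar_year = year_of(sw$first_study),
        switch_date = sw$first_study)
    }
  }
  cohort <- rbindlist(out)
  if (!nrow(cohort)) {
    d <- firsts$issue_date[0L]
    cohort <- data.table(patient_id = firsts$patient_id[0L],
                         role = character(0), entry_date = d,
                         index_date = d, prior_comparator_rx = integer(0),
                         time_since_entry_days = integer(0),
                         calendar_year = integer(0), switch_date = d)
  }
  setorder(cohort, patient_id, entry_date, role)
  cohort <- as.data.frame(cohort)
  attr(cohort, "exclusions") <- excl
  cohort
}

as_window <- function(window) {
  if (length(window) != 2L) stop("window must have a start and an end")
  if (inherits(window, "character")) window <- as.Date(window)
  if (window[1L] >= window[2L]) stop("window start must precede its end")
  window
}

year_of <- function(d) {
  if (inherits(d, "Date")) as.integer(format(d, "%Y")) else as.integer(d %/% 365)
}

na_like <- function(d) {
  if (inherits(d, "Date")) as.Date(NA) else NA_real_
}
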