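#' Exposure-set definition
#'
#' The three ways of defining "similar prior comparator use" when forming the
#' pool of potential comparators for a study-drug user:
#' \describe{
#'   \item{prescription}{same number of prior comparator prescriptions.}
#'   \item{time}{time since base-cohort entry within `caliper_days` of the
#'     study-drug user's.}
#'   \item{hybrid}{same prior-prescription count, time since entry within the
#'     caliper, and the same calendar year of the index date.}
#' }
#' The caliper comparison is inclusive (a closed interval).
#'
#' @param kind one of "prescription", "time", "hybrid".
#' @param caliper_days positive integer caliper on the time-since-entry scale
#'   (default 30; ignored for the prescription kind).
#' @return An object of class `pnu_expdef`.
#' @export
exposure_definition <- function(kind = c("hybrid", "prescription", "time"),
                                caliper_days = 30L) {
  kind <- match.arg(kind)
  if (caliper_days < 1) stop("caliper_days must be positive")
  structure(list(kind = kind, caliper_days = as.integer(caliper_days),
                 require_same_calendar_year = kind == "hybrid"),
            class = "pnu_expdef")
}

#' Candidate comparator index prescriptions
#'
#' For every comparator membership of the base cohort, one candidate row per
#' comparator prescription from cohort entry up to (and excluding) any switch
#' to the study drug. Each candidate carries the quantities the exposure-set
#' predicates compare: the number of comparator prescriptions issued strictly
#' before it, days since the patient's own base-cohort entry, and the
#' calendar year of the prescription.
#'
#' @param cohort output of [classify_new_users()].
#' @param prescriptions prescription table.
#' @return data.frame `patient_id`, `index_date`, `k` (prior comparator
#'   prescriptions), `dt_entry` (days since own entry), `year`.
#' @export
comparator_candidates <- function(cohort, prescriptions) {
  comp <- as.data.table(cohort)[role == "comparator",
                                .(patient_id, entry_date, switch_date)]
  rx <- as.data.table(prescriptions)[drug_class == "comparator",
                                     .(patient_id, issue_date)]
  setorder(rx, patient_id, issue_date)
  rx[, k := seq_len(.N) - 1L, by = patient_id]
  cand <- rx[comp, on = .(patient_id), nomatch = NULL]
  cand <- cand[issue_date >= entry_date &
                 (is.na(switch_date) | issue_date < switch_date)]
  cand[, `:=`(index_date = issue_date,
              dt_entry = as.integer(issue_date - entry_date),
              year = year_of(issue_date))]
  as.data.frame(cand[, .(patient_id, index_date, k, dt_entry, year)])
}

#' Build exposure sets for every study-drug user
#'
#' One exposure set per study-drug user (incident or prevalent), holding the
#' pool of comparator index prescriptions that satisfy the chosen
#' definition's predicates relative to the treated user. A comparator patient
#' may contribute candidate prescriptions to many sets; uniqueness is
#' enforced later, at matching. Sets with no eligible candidate are retained
#' and flagged so the match-rate diagnostic keeps its denominator.
#'
#' Because every definition's predicates select an interval of the
#' time-since-entry scale within a (prior-count, calendar-year) group, sets
#' are stored implicitly: one shared candidate table, sorted so that each
#' set's pool is a contiguous row range located by binary search. This keeps
#' memory linear in the number of candidate prescriptions rather than in the
#' sum of pool sizes (which reaches tens of millions of rows in cohorts of a
#' few tens of thousands of patients). Use [expsets_members()] to materialize
#' the long member table when its size is manageable.
#'
#' A treated user's own pre-switch comparator prescriptions are never
#' eligible for their own set; they are masked wherever pools are consumed.
#'
#' @param cohort output of [classify_new_users()].
#' @param prescriptions prescription table.
#' @param definition an [exposure_definition()].
#' @return Object of class `pnu_exposure_sets`: list with
#'   \describe{
#'     \item{sets}{one row per treated user, in chronological index-date
#'       order: `set_id`, `treated_patient_id`, `treated_index_date`,
#'       `treated_role`, `k`, `dt_entry`, `year`, `from`, `to` (candidate
#'       row range; NA when empty), `n_candidates` (self-candidates
#'       excluded).}
#'     \item{candidates}{the shared candidate table (see
#'       [comparator_candidates()]), sorted for range lookup.}
#'     \item{definition}{the definition used.}
#'   }
#' @export
build_exposure_sets <- function(cohort, prescriptions, definition) {
  stopifnot(inherits(definition, "pnu_expdef"))
  co <- as.data.table(cohort)
  tr <- co[role %in% c("incident_study", "prevalent_study"),
           .(treated_patient_id = patient_id,
             treated_index_date = index_date,
             treated_role = role, k = prior_comparator_rx,
             dt_entry = time_since_entry_days, year = calendar_year)]
  setorder(tr, treated_index_date, treated_patient_id)
  tr[, set_id := seq_len(.N)]
  setcolorder(tr, "set_id")
  cand <- as.data.table(comparator_candidates(cohort, prescriptions))
  cal <- definition$caliper_days

  n <- nrow(tr)
  from <- rep(NA_integer_, n); to <- rep(NA_integer_, n)
  if (nrow(cand)) {
    if (definition$kind == "prescription") {
      setorder(cand, k, patient_id, index_date)
      gb <- cand[, .(gs = .I[1L], ge = .I[.N]), by = k]
      gi <- gb[tr, on = .(k)]
      from <- gi$gs; to <- gi$ge
    } else if (definition$kind == "time") {
      setorder(cand, dt_entry, patient_id, index_date)
      from <- findInterval(tr$dt_entry - cal - 1L, cand$dt_entry) + 1L
      to <- findInterval(tr$dt_entry + cal, cand$dt_entry)
    } else { # hybrid
      setorder(cand, k, year, dt_entry, patient_id, index_date)
      gb <- cand[, .(gs = .I[1L], ge = .I[.N]), by = .(k, year)]
      gi <- gb[tr, on = .(k, year)]
      dts <- cand$dt_entry
      for (i in seq_len(n)) {
        gs <- gi$gs[i]
        if (is.na(gs)) next
        slice <- dts[gs:gi$ge[i]]
        f <- findInterval(tr$dt_entry[i] - cal - 1L, slice) + 1L
        t2 <- findInterval(tr$dt_entry[i] + cal, slice)
        if (t2 >= f) { from[i] <- gs + f - 1L; to[i] <- gs + t2 - 1L }
      }
    }
  }
  empty <- is.na(from) | is.na(to) | to < from
  from[empty] <- NA_integer_; to[empty] <- NA_integer_

  # pool sizes, excluding the treated user's own candidate prescriptions
  n_self <- integer(n)
  if (nrow(cand)) {
    rows_by_patient <- split(seq_len(nrow(cand)), cand$patient_id)
    pidx <- match(as.character(tr$treated_patient_id),
                  names(rows_by_patient))
    for (i in seq_len(n)) {
      if (is.na(from[i]) || is.na(pidx[i])) next
      r <- rows_by_patient[[pidx[i]]]
      n_self[i] <- sum(r >= from[i] & r <= to[i])
    }
  }
  tr[, `:=`(from = from, to = to,
            n_candidates = fifelse(is.na(from), 0L,
                                   to - from + 1L - n_self))]

  structure(list(sets = tr, candidates = cand, definition = definition),
            class = "pnu_exposure_sets")
}

# row indices of one set's eligible candidates (self-candidates masked);
# integer(0) for empty sets
set_candidate_rows <- function(expsets, i) {
  s <- expsets$sets
  if (is.na(s$from[i])) return(integer(0))
  rows <- s$from[i]:s$to[i]
  rows[expsets$candidates$patient_id[rows] != s$treated_patient_id[i]]
}

#' Materialize the long member table of an exposure-set object
#'
#' Expands the implicit range representation of [build_exposure_sets()] into
#' one row per set member (the treated row plus every eligible candidate).
#' Intended for inspection, export and desk-scale analyses; the table grows
#' with the sum of pool sizes.
#'
#' @param expsets a `pnu_exposure_sets` object.
#' @return data.frame: `set_id`, `patient_id`, `index_date`, `k`,
#'   `dt_entry`, `year`, `is_treated`.
#' @export
expsets_members <- function(expsets) {
  stopifnot(inherits(expsets, "pnu_exposure_sets"))
  s <- expsets$sets
  idx <- lapply(seq_len(nrow(s)), function(i) set_candidate_rows(expsets, i))
  lens <- lengths(idx)
  m <- expsets$candidates[unlist(idx)]
  m[, `:=`(set_id = rep(s$set_id, lens), is_treated = 0L)]
  treated_rows <- s[, .(patient_id = treated_patient_id,
                        index_date = treated_index_date, k, dt_entry, year,
                        set_id, is_treated = 1L)]
  members <- rbind(treated_rows, m)
  setorder(members, set_id, -is_treated, index_date, patient_id)
  setcolorder(members, c("set_id", "patient_id", "index_date", "k",
                         "dt_entry", "year", "is_treated"))
  as.data.frame(members)
}

#' @export
print.pnu_exposure_sets <- function(x, ...) {
  cat("<pnu_exposure_sets>", nrow(x$sets), "sets (",
      x$definition$kind, "definition )\n")
  cat("  empty sets:", sum(x$sets$n_candidates == 0L),
      " median pool size:", stats::median(x$sets$n_candidates), "\n")
  invisible(x)
}
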