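#' Within-set positivity screening
#'
#' A treated user's TCPS must lie within the (inclusive) range of the TCPSs
#' of the potential comparators in the same exposure set, assessed on all
#' members, not only the sampled ones. Sets violating the rule — for
#' instance a treated score of 0.75 against a comparator range of 0.24 to
#' 0.65 — are dropped before matching; sets with no candidates are dropped
#' with reason `no_candidates`.
#'
#' @param scores a `pnu_tcps_scores` object from [predict_tcps()].
#' @return data.frame, one row per set: `set_id`, `treated_score`,
#'   `comparator_score_min`, `comparator_score_max`, `kept`, `reason`.
#' @export
check_positivity <- function(scores) {
  stopifnot(inherits(scores, "pnu_tcps_scores"))
  es <- scores$expsets
  s <- es$sets
  n <- nrow(s)
  lo <- rep(NA_real_, n); hi <- rep(NA_real_, n)
  cs <- scores$candidate_score
  for (i in seq_len(n)) {
    rows <- set_candidate_rows(es, i)
    if (!length(rows)) next
    lo[i] <- min(cs[rows]); hi[i] <- max(cs[rows])
  }
  ts <- scores$treated_score
  kept <- !is.na(lo) & ts >= lo & ts <= hi
  data.frame(set_id = s$set_id, treated_score = ts,
             comparator_score_min = lo, comparator_score_max = hi,
             kept = kept,
             reason = ifelse(is.na(lo), "no_candidates",
                             ifelse(kept, "", "outside_comparator_range")))
}

#' Chronological 1:1 nearest-TCPS matching without replacement
#'
#' Processes treated users in ascending index-date order (ties by patient
#' id). Within each surviving exposure set, the still-available comparator
#' candidate with the smallest absolute TCPS difference is selected; exact
#' score ties go to the earlier candidate index date, then the smaller
#' patient id. Matching is without replacement at the comparator-person
#' level: once a comparator patient is selected, all of their candidate
#' prescriptions become unavailable in every remaining set. Treated users in
#' positivity-dropped sets, empty sets, or sets whose candidates were all
#' taken are logged unmatched with a reason code.
#'
#' @param scores a `pnu_tcps_scores` object from [predict_tcps()].
#' @param positivity report from [check_positivity()]; computed from
#'   `scores` when NULL.
#' @return list with `pairs` (one row per matched pair: `pair_id`, `set_id`,
#'   treated and comparator ids, index dates, role and scores) and
#'   `unmatched` (`set_id`, `treated_patient_id`, `treated_role`, `reason`
#'   in dropped_positivity / empty_set / exhausted_candidates).
#' @export
match_chronological <- function(scores, positivity = NULL) {
  stopifnot(inherits(scores, "pnu_tcps_scores"))
  if (is.null(positivity)) positivity <- check_positivity(scores)
  es <- scores$expsets
  st <- es$sets
  # chronological processing order (ties by treated patient id), without
  # assuming the sets table is pre-sorted
  ord <- order(st$treated_index_date, st$treated_patient_id)
  kept_vec <- positivity$kept[match(st$set_id, positivity$set_id)]
  ts_vec <- scores$treated_score

  cand <- es$candidates
  c_score <- scores$candidate_score
  c_pid <- cand$patient_id
  c_date <- cand$index_date
  comp_ids <- unique(c_pid)
  used <- logical(length(comp_ids))
  c_idx <- match(c_pid, comp_ids)

  n <- nrow(st)
  m_pid <- c_pid[NA_integer_][rep(1L, n)]
  m_date <- c_date[NA_integer_][rep(1L, n)]
  m_score <- rep(NA_real_, n)
  reason <- rep(NA_character_, n)
  for (i in ord) {
    rows <- set_candidate_rows(es, i)
    if (!length(rows)) { reason[i] <- "empty_set"; next }
    if (!isTRUE(kept_vec[i])) { reason[i] <- "dropped_positivity"; next }
    rows <- rows[!used[c_idx[rows]]]
    if (!length(rows)) { reason[i] <- "exhausted_candidates"; next }
    d <- abs(c_score[rows] - ts_vec[i])
    dmin <- min(d)
    tie <- rows[d == dmin]
    best <- if (length(tie) == 1L) tie
            else tie[order(c_date[tie], c_pid[tie])[1L]]
    used[c_idx[best]] <- TRUE
    m_pid[i] <- c_pid[best]; m_date[i] <- c_date[best]
    m_score[i] <- c_score[best]
  }

  mo <- ord[!is.na(m_pid[ord])] # matched, in chronological order
  uo <- ord[is.na(m_pid[ord])]
  pairs <- data.frame(
    pair_id = seq_along(mo),
    set_id = st$set_id[mo],
    treated_patient_id = st$treated_patient_id[mo],
    treated_index_date = st$treated_index_date[mo],
    treated_role = st$treated_role[mo],
    comparator_patient_id = m_pid[mo],
    comparator_index_date = m_date[mo],
    treated_score = ts_vec[mo],
    comparator_score = m_score[mo]
  )
  unmatched <- data.frame(
    set_id = st$set_id[uo],
    treated_patient_id = st$treated_patient_id[uo],
    treated_role = st$treated_role[uo],
    reason = reason[uo]
  )
  list(pairs = pairs, unmatched = unmatched)
}

#' Match-rate diagnostic
#'
#' Proportion of study-drug users successfully matched, overall and by
#' new-user subgroup.
#'
#' @param match result of [match_chronological()].
#' @return data.frame with `group`, `n_treated`, `n_matched`, `match_rate`.
#' @export
match_rate <- function(match) {
  tab <- function(group, pairs_n, total_n)
    data.frame(group = group, n_treated = total_n, n_matched = pairs_n,
               match_rate = if (total_n > 0) pairs_n / total_n else NA_real_)
  roles <- c(overall = NA, incident = "incident_study",
             prevalent = "prevalent_study")
  out <- lapply(names(roles), function(g) {
    r <- roles[[g]]
    p <- if (is.na(r)) nrow(match$pairs) else
      sum(match$pairs$treated_role == r)
    u <- if (is.na(r)) nrow(match$unmatched) else
      sum(match$unmatched$treated_role == r)
    tab(g, p, p + u)
  })
  do.call(rbind, out)
}
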