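# Independent reference implementations used to check the package's
# computational routines. Deliberately naive: explicit day enumeration,
# term-by-term sums and plain loops, sharing no code with the package.

# --- treatment episodes: day-coverage oracle ---------------------------
# mark every day covered by a supply interval [issue, issue + supply) or
# lying within `grace` days after a covered day; maximal runs are episodes
oracle_episodes <- function(issue, supply, grace) {
  stopifnot(length(issue) == length(supply))
  days <- integer(0)
  for (i in seq_along(issue))
    days <- union(days, seq(issue[i], issue[i] + supply[i] + grace - 1L))
  days <- sort(days)
  breaks <- c(0L, which(diff(days) > 1L), length(days))
  out <- NULL
  for (b in seq_len(length(breaks) - 1L)) {
    run <- days[(breaks[b] + 1L):breaks[b + 1L]]
    in_run <- issue >= run[1L] & issue <= run[length(run)]
    out <- rbind(out, data.frame(
      start = min(issue[in_run]),
      supply_end = max(issue[in_run] + supply[in_run]),
      episode_end = run[length(run)] + 1L))
  }
  out
}

# --- weighted conditional-logit: brute-force enumeration ----------------
oracle_clogit_loglik <- function(beta, X, is_treated, weight, set_id) {
  ll <- 0
  for (s in unique(set_id)) {
    rows <- which(set_id == s)
    if (sum(is_treated[rows] == 0L) == 0L) next # uninformative set
    denom <- 0
    eta_t <- NA_real_
    for (r in rows) {
      eta <- sum(X[r, ] * beta)
      w <- if (is_treated[r] == 1L) 1 else weight[r]
      denom <- denom + w * exp(eta)
      if (is_treated[r] == 1L) eta_t <- eta
    }
    ll <- ll + eta_t - log(denom)
  }
  ll
}

num_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(j) {
    hi <- x; hi[j] <- hi[j] + h
    lo <- x; lo[j] <- lo[j] - h
    (f(hi) - f(lo)) / (2 * h)
  }, numeric(1L))
}

# --- Cox partial likelihood (Breslow), written out explicitly -----------
oracle_cox_loglik <- function(beta, time, status, x) {
  ll <- 0
  for (t in sort(unique(time[status == 1L]))) {
    ev <- which(time == t & status == 1L)
    risk <- which(time >= t)
    ll <- ll + sum(x[ev] * beta) -
      length(ev) * log(sum(exp(x[risk] * beta)))
  }
  ll
}

# --- fixture builders ---------------------------------------------------

# exposure-set object from an explicit per-set candidate list (sets are laid
# out contiguously in one candidate table)
manual_expsets <- function(sets, candidates_by_set,
                           definition = exposure_definition("hybrid", 30)) {
  stopifnot(nrow(sets) == length(candidates_by_set))
  cand <- do.call(rbind, candidates_by_set)
  lens <- vapply(candidates_by_set, nrow, integer(1L))
  to <- cumsum(lens)
  from <- to - lens + 1L
  from[lens == 0L] <- NA_integer_
  to[lens == 0L] <- NA_integer_
  s <- data.table::as.data.table(sets)
  s[, `:=`(from = from, to = to)]
  n_self <- vapply(seq_len(nrow(s)), function(i) {
    if (is.na(from[i])) return(0L)
    sum(cand$patient_id[from[i]:to[i]] == s$treated_patient_id[i])
  }, integer(1L))
  s[, n_candidates := data.table::fifelse(is.na(from), 0L,
                                          lens - n_self)]
  structure(list(sets = s,
                 candidates = data.table::as.data.table(cand),
                 definition = definition),
            class = "pnu_exposure_sets")
}

manual_scores <- function(expsets, treated_score, candidate_score) {
  structure(list(expsets = expsets, candidate_score = candidate_score,
                 treated_score = treated_score),
            class = "pnu_tcps_scores")
}

# one candidate-table row (length-0 patient_id gives an empty pool)
cand_row <- function(patient_id, index_date = 0, k = 0L, dt_entry = 0L,
                     year = 2000L) {
  n <- length(patient_id)
  data.frame(patient_id = patient_id,
             index_date = rep_len(index_date, n),
             k = rep_len(k, n), dt_entry = rep_len(dt_entry, n),
             year = rep_len(year, n))
}

# one treated (set) row
set_row <- function(set_id, patient_id, index_date = 0,
                    role = "incident_study", k = 0L, dt_entry = 0L,
                    year = 2000L) {
  data.frame(set_id = set_id, treated_patient_id = patient_id,
             treated_index_date = index_date, treated_role = role,
             k = k, dt_entry = dt_entry, year = year)
}

# random small matching instance: shared comparator persons across sets,
# random scores; used for greedy-replay and uniqueness properties
random_match_instance <- function(seed) {
  set.seed(seed)
  n_sets <- sample(2:8, 1L)
  n_comp <- sample(3:12, 1L)
  sets <- do.call(rbind, lapply(seq_len(n_sets), function(s) {
    set_row(s, patient_id = 1000L + s, index_date = sample(0:200, 1L))
  }))
  cands <- lapply(seq_len(n_sets), function(s) {
    pool <- sample(n_comp, sample(0:min(5L, n_comp), 1L))
    if (!length(pool)) return(cand_row(integer(0), numeric(0)))
    do.call(rbind, lapply(pool, function(p)
      cand_row(p, index_date = sample(0:200, 1L))))
  })
  es <- manual_expsets(sets, cands)
  manual_scores(es,
                treated_score = runif(n_sets),
                candidate_score = runif(nrow(es$candidates)))
}

# naive greedy matcher on a scores object, with simple data structures
oracle_greedy_match <- function(scores, positivity) {
  es <- scores$expsets
  s <- as.data.frame(es$sets)
  cand <- as.data.frame(es$candidates)
  taken <- c()
  out <- list()
  for (i in order(s$treated_index_date, s$treated_patient_id)) {
    if (!positivity$kept[match(s$set_id[i], positivity$set_id)]) next
    if (is.na(s$from[i])) next
    rows <- s$from[i]:s$to[i]
    rows <- rows[cand$patient_id[rows] != s$treated_patient_id[i]]
    rows <- rows[!(cand$patient_id[rows] %in% taken)]
    if (!length(rows)) next
    d <- abs(scores$candidate_score[rows] - scores$treated_score[i])
    best <- rows[order(d, cand$index_date[rows], cand$patient_id[rows])][1L]
    taken <- c(taken, cand$patient_id[best])
    out[[length(out) + 1L]] <- data.frame(
      set_id = s$set_id[i], comparator_patient_id = cand$patient_id[best],
      comparator_index_date = cand$index_date[best])
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(set_id = integer(0), comparator_patient_id = integer(0),
               comparator_index_date = numeric(0))
}
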