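#' Standardized mean differences
#'
#' Balance metrics between two groups. `smd_continuous()` uses
#' `|m_a - m_b| / sqrt((s_a^2 + s_b^2) / 2)`; `smd_binary()` uses
#' `|p_a - p_b| / sqrt((p_a(1-p_a) + p_b(1-p_b)) / 2)`; `smd_categorical()`
#' is the multivariate Mahalanobis-type standardized difference over the
#' L - 1 non-reference level indicators, so a multi-level covariate yields a
#' single nonnegative number. `smd()` dispatches on data vectors, treating a
#' numeric with more than two distinct values as continuous, a two-level
#' variable as binary, and anything else as categorical (missing values
#' become an explicit `missing` level). Zero pooled variance with unequal
#' means returns `Inf` with a warning.
#'
#' @param mean_a,sd_a,mean_b,sd_b group means and standard deviations.
#' @param p_a,p_b group proportions: scalars for `smd_binary()` (optionally
#'   given as `count / n` via `n_a`, `n_b`), per-level proportion vectors
#'   summing to 1 for `smd_categorical()`.
#' @param n_a,n_b optional totals when `p_a`, `p_b` are counts.
#' @param a,b data vectors for the two groups.
#' @param kind force "continuous", "binary" or "categorical" in `smd()`.
#' @return Nonnegative absolute standardized difference.
#' @export
#' @examples
#' smd_continuous(69.64, 11.85, 69.58, 11.91) # 0.005 to 3 d.p.
#' smd_binary(10543, 10625, n_a = 33065, n_b = 33065) # 0.005 to 3 d.p.
smd_continuous <- function(mean_a, sd_a, mean_b, sd_b) {
  pooled <- sqrt((sd_a^2 + sd_b^2) / 2)
  if (pooled == 0) {
    if (mean_a == mean_b) return(0)
    warning("zero pooled variance with unequal means")
    return(Inf)
  }
  abs(mean_a - mean_b) / pooled
}

#' @rdname smd_continuous
#' @export
smd_binary <- function(p_a, p_b, n_a = NULL, n_b = NULL) {
  if (!is.null(n_a)) p_a <- p_a / n_a
  if (!is.null(n_b)) p_b <- p_b / n_b
  pooled <- sqrt((p_a * (1 - p_a) + p_b * (1 - p_b)) / 2)
  if (pooled == 0) {
    if (p_a == p_b) return(0)
    warning("zero pooled variance with unequal proportions")
    return(Inf)
  }
  abs(p_a - p_b) / pooled
}

#' @rdname smd_continuous
#' @export
smd_categorical <- function(p_a, p_b) {
  stopifnot(length(p_a) == length(p_b), length(p_a) >= 2L)
  pa <- as.numeric(p_a[-1L]); pb <- as.numeric(p_b[-1L])
  d <- pa - pb
  cov_of <- function(p) diag(p, nrow = length(p)) - tcrossprod(p)
  S <- (cov_of(pa) + cov_of(pb)) / 2
  Sinv <- tryCatch(solve(S), error = function(e) {
    sv <- svd(S)
    pos <- sv$d > max(sv$d) * 1e-10
    sv$v[, pos, drop = FALSE] %*% diag(1 / sv$d[pos], sum(pos)) %*%
      t(sv$u[, pos, drop = FALSE])
  })
  val <- drop(t(d) %*% Sinv %*% d)
  if (val < 0 && val > -1e-12) val <- 0
  sqrt(val)
}

#' @rdname smd_continuous
#' @export
smd <- function(a, b, kind = NULL) {
  if (is.null(kind)) {
    vals <- unique(c(a, b))
    vals <- vals[!is.na(vals)]
    kind <- if (is.numeric(a) && length(vals) > 2L) "continuous"
            else if (length(vals) <= 2L && !anyNA(c(a, b))) "binary"
            else "categorical"
  }
  switch(kind,
    continuous = smd_continuous(mean(a), sd(a), mean(b), sd(b)),
    binary = {
      lv <- sort(unique(c(a, b)))
      smd_binary(mean(a == lv[length(lv)]), mean(b == lv[length(lv)]))
    },
    categorical = {
      av <- as.character(a); bv <- as.character(b)
      av[is.na(av)] <- "missing"; bv[is.na(bv)] <- "missing"
      lev <- sort(unique(c(av, bv)))
      if (length(lev) < 2L) return(0)
      smd_categorical(prop.table(table(factor(av, lev))),
                      prop.table(table(factor(bv, lev))))
    },
    stop("unknown kind: ", kind)
  )
}

#' Random unmatched comparator descriptive sample
#'
#' Draws exactly one comparator candidate prescription uniformly from each
#' nonempty exposure set, before matching — the descriptive "unmatched
#' comparator" group against which the matched cohort is contrasted.
#'
#' @param expsets a [build_exposure_sets()] result.
#' @param seed integer seed; the draw is reproducible.
#' @return data.frame of sampled candidate rows (`set_id`, `patient_id`,
#'   `index_date`, `k`, `dt_entry`, `year`).
#' @export
sample_unmatched_group <- function(expsets, seed = 1L) {
  stopifnot(inherits(expsets, "pnu_exposure_sets"))
  set.seed(seed)
  n <- nrow(expsets$sets)
  pick <- integer(0); sids <- expsets$sets$set_id[0L]
  for (i in seq_len(n)) {
    rows <- set_candidate_rows(expsets, i)
    if (!length(rows)) next
    pick <- c(pick, rows[sample.int(length(rows), 1L)])
    sids <- c(sids, expsets$sets$set_id[i])
  }
  out <- expsets$candidates[pick]
  out[, set_id := sids]
  setcolorder(out, "set_id")
  as.data.frame(out)
}

#' Covariate balance table for a matched PNU cohort
#'
#' One row per covariate, summarising the unmatched comparator sample, the
#' matched comparator arm and the matched study arm, with two absolute
#' standardized differences: `asd_unmatched` contrasts the matched study arm
#' with the random unmatched comparator sample (imbalance before matching)
#' and `asd_matched` contrasts the two matched arms (the balance the design
#' achieved; below 0.1 is the conventional adequacy threshold).
#'
#' @param pairs matched pairs from [match_chronological()].
#' @param unmatched unmatched comparator sample from
#'   [sample_unmatched_group()].
#' @param patients patient table carrying the covariates.
#' @param covariates character vector of covariate columns (default: all
#'   non-identifier, non-date columns).
#' @return data.frame: `covariate`, `kind`, group summaries (mean (SD) for
#'   continuous, proportion for binary, NA for multi-level), `asd_unmatched`,
#'   `asd_matched`.
#' @export
balance_table <- function(pairs, unmatched, patients, covariates = NULL) {
  if (is.null(covariates))
    covariates <- setdiff(names(patients),
                          c("patient_id", "registration_date", "death_date",
                            "transfer_date"))
  pull <- function(ids, col) {
    patients[[col]][match(ids, patients$patient_id)]
  }
  g_un <- unmatched$patient_id
  g_mc <- pairs$comparator_patient_id
  g_ms <- pairs$treated_patient_id
  rows <- lapply(covariates, function(cv) {
    a <- pull(g_ms, cv); b <- pull(g_mc, cv); u <- pull(g_un, cv)
    vals <- unique(c(a, b, u)); vals <- vals[!is.na(vals)]
    kind <- if (is.numeric(a) && length(vals) > 2L) "continuous"
            else if (length(vals) <= 2L && !anyNA(c(a, b, u))) "binary"
            else "categorical"
    summ <- function(x) switch(kind,
      continuous = sprintf("%.2f (%.2f)", mean(x), sd(x)),
      binary = sprintf("%.3f", mean(x == max(vals))),
      categorical = NA_character_)
    data.frame(covariate = cv, kind = kind,
               unmatched_comparator = summ(u),
               matched_comparator = summ(b), matched_study = summ(a),
               asd_unmatched = smd(a, u, kind),
               asd_matched = smd(a, b, kind))
  })
  do.call(rbind, rows)
}
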