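#' Run the full prevalent new-user analysis
#'
#' Orchestrates the complete design for one or more exposure-set
#' configurations: base-cohort assembly, exposure-set construction, within-set
#' sampling, TCPS estimation, positivity screening, chronological 1:1
#' matching, the unmatched descriptive sample, as-treated follow-up, Cox
#' effect estimation (overall and by new-user subgroup) and the balance
#' table. Each requested definition is crossed with each caliper (the
#' prescription-based definition ignores calipers and runs once, with a
#' notice); a failure in one configuration is recorded and the others
#' proceed. Stage seeds are split deterministically from the master seed, so
#' an identical call reproduces the report exactly.
#'
#' @param patients,prescriptions,events the three analysis tables (see
#'   [generate_population()] for the schema).
#' @param window length-2 cohort-entry window (start, end).
#' @param washout_days required drug-free registered history before entry
#'   (default 365).
#' @param grace_days grace period for treatment episodes and discontinuation
#'   (default 30).
#' @param definitions subset of `c("prescription", "time", "hybrid")`.
#' @param calipers numeric vector of time-since-entry calipers in days
#'   (default 30; add 15 for the narrower sensitivity analysis).
#' @param target_per_set comparator sampling target per exposure set
#'   (default 50).
#' @param covariates covariate columns for the TCPS model and balance table
#'   (default: all non-identifier, non-date patient columns).
#' @param study_end administrative end of follow-up (default: window end).
#' @param cluster_by_pair cluster the Cox sandwich variance on matched pair
#'   (default FALSE).
#' @param ridge L2 penalty for the TCPS fit (default 0).
#' @param seed master seed for all stage-level randomness.
#' @return Object of class `pnu_report`: list of per-configuration results
#'   (`cohort_counts`, `match_rates`, `positivity_dropped`, `effects`,
#'   `balance`, `tcps_model`, or `error`), plus the shared `cohort` and
#'   call parameters. `report_table()` flattens the effect estimates.
#' @export
run_pnu <- function(patients, prescriptions, events,
                    window = c(as.Date("2000-01-01"), as.Date("2004-12-31")),
                    washout_days = 365L, grace_days = 30L,
                    definitions = "hybrid", calipers = 30L,
                    target_per_set = 50L, covariates = NULL,
                    study_end = NULL, cluster_by_pair = FALSE, ridge = 0,
                    seed = 1L) {
  window <- as_window(window)
  if (is.null(study_end)) study_end <- window[2L]
  definitions <- match.arg(definitions,
                           c("prescription", "time", "hybrid"),
                           several.ok = TRUE)
  if (any(calipers < 1)) stop("calipers must be positive")

  set.seed(seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1L,
                            2L * length(definitions) * length(calipers))

  cohort <- classify_new_users(patients, prescriptions, window, washout_days)
  episodes <- build_episodes(prescriptions, grace_days)
  n_roles <- table(cohort$role)

  grid <- expand.grid(definition = definitions, caliper = calipers,
                      stringsAsFactors = FALSE)
  if (sum(grid$definition == "prescription") > 1L)
    message("prescription-based definition ignores the caliper; ",
            "running it once")
  grid <- grid[!(grid$definition == "prescription" &
                   duplicated(grid$definition)), , drop = FALSE]

  configs <- list()
  for (i in seq_len(nrow(grid))) {
    defn <- grid$definition[i]
    cal <- grid$caliper[i]
    label <- if (defn == "prescription") defn
             else paste0(defn, "_", cal, "d")
    s1 <- stage_seeds[2L * i - 1L]
    s2 <- stage_seeds[2L * i]
    configs[[label]] <- tryCatch({
      expsets <- build_exposure_sets(cohort, prescriptions,
                                     exposure_definition(defn, cal))
      stacked <- sample_within_sets(expsets, target_per_set, seed = s1)
      tcps_data <- build_tcps_data(stacked, patients, covariates)
      model <- fit_tcps(tcps_data, ridge = ridge)
      scores <- predict_tcps(model, expsets, patients)
      pos <- check_positivity(scores)
      match <- match_chronological(scores, pos)
      unmatched_grp <- sample_unmatched_group(expsets, seed = s2)
      fu <- build_followup(match$pairs, episodes, events, patients, cohort,
                           study_end)
      effects <- lapply(c("overall", "prevalent", "incident"),
                        function(g) fit_cox_robust(fu, g, cluster_by_pair))
      names(effects) <- c("overall", "prevalent", "incident")
      bal <- balance_table(match$pairs, unmatched_grp, patients, covariates)
      list(definition = defn, caliper = cal,
           n_sets = nrow(expsets$sets),
           n_empty_sets = sum(expsets$sets$n_candidates == 0L),
           positivity_dropped = sum(!pos$kept),
           match_rates = match_rate(match),
           n_pairs = nrow(match$pairs),
           effects = effects, balance = bal,
           tcps_model = model, followup = fu,
           pairs = match$pairs, unmatched = match$unmatched)
    }, error = function(e) list(definition = defn, caliper = cal,
                                error = conditionMessage(e)))
  }

  structure(list(configs = configs, cohort = cohort,
                 cohort_counts = as.list(n_roles),
                 window = window, study_end = study_end, seed = seed),
            class = "pnu_report")
}

#' Flatten a PNU report into a forest-plot-style table
#'
#' @param report a `pnu_report` from [run_pnu()].
#' @return data.frame with one row per configuration and subgroup:
#'   `definition`, `caliper`, `subgroup`, `hr`, `ci_low`, `ci_high`,
#'   `confidence_limit_ratio`, `n_events_study`, `n_events_comparator`,
#'   `match_rate`.
#' @export
report_table <- function(report) {
  stopifnot(inherits(report, "pnu_report"))
  rows <- list()
  for (label in names(report$configs)) {
    cf <- report$configs[[label]]
    if (!is.null(cf$error)) next
    mr <- cf$match_rates$match_rate[cf$match_rates$group == "overall"]
    for (g in names(cf$effects)) {
      e <- cf$effects[[g]]
      rows[[paste(label, g)]] <- data.frame(
        definition = cf$definition, caliper = cf$caliper, subgroup = g,
        hr = e$hr, ci_low = e$ci95[1L], ci_high = e$ci95[2L],
        confidence_limit_ratio = e$confidence_limit_ratio,
        n_events_study = e$n_events_study,
        n_events_comparator = e$n_events_comparator,
        match_rate = mr)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.pnu_report <- function(x, ...) {
  cat("<pnu_report>", length(x$configs), "configuration(s); base cohort:\n")
  cc <- x$cohort_counts
  cat(sprintf("  incident study %s | prevalent study %s | comparator %s\n",
              cc$incident_study %||% 0, cc$prevalent_study %||% 0,
              cc$comparator %||% 0))
  tab <- report_table(x)
  if (!is.null(tab)) {
    tab$hr <- sprintf("%.2f (%.2f-%.2f)", tab$hr, tab$ci_low, tab$ci_high)
    print(tab[, c("definition", "caliper", "subgroup", "hr",
                  "confidence_limit_ratio", "match_rate")], digits = 3)
  }
  for (label in names(x$configs))
    if (!is.null(x$configs[[label]]$error))
      cat("  FAILED", label, ":", x$configs[[label]]$error, "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
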