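#' Sample comparator candidates within exposure sets
#'
#' Draws the within-set comparator samples used to fit the TCPS model at
#' reduced computational cost. In the default per-set mode the sampling
#' fraction is `f = min(1, target_per_set / pool size)`, so about
#' `target_per_set` comparator prescriptions are sampled from each large set
#' and every candidate is kept in small sets; each sampled comparator row
#' carries the inverse-sampling-fraction weight `1/f`, and weight times
#' fraction is exactly 1. The treated row of every set is always included
#' with weight 1. A single global-fraction mode is also available.
#'
#' @param expsets a [build_exposure_sets()] result.
#' @param target_per_set desired comparator sample size per set (default 50).
#' @param seed integer seed; sampling is reproducible given the seed.
#' @param mode `"per_set"` (default) or `"global"`.
#' @param global_fraction sampling fraction in (0, 1] used when
#'   `mode = "global"` (at least one candidate is always kept per nonempty
#'   set).
#' @return data.frame of stacked rows: `set_id`, `patient_id`, `index_date`,
#'   `k`, `dt_entry`, `year`, `is_treated`, `weight`.
#' @export
sample_within_sets <- function(expsets, target_per_set = 50L, seed = 1L,
                               mode = c("per_set", "global"),
                               global_fraction = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(expsets, "pnu_exposure_sets"), target_per_set >= 1)
  if (mode == "global" &&
      (is.null(global_fraction) || global_fraction <= 0 ||
         global_fraction > 1))
    stop("global mode needs a fraction in (0, 1]")
  set.seed(seed)
  s <- expsets$sets
  n <- nrow(s)
  idx <- vector("list", n)
  wt <- numeric(n)
  for (i in seq_len(n)) {
    rows <- set_candidate_rows(expsets, i)
    m <- length(rows)
    if (!m) next
    n_keep <- if (mode == "per_set") min(m, as.integer(target_per_set))
              else max(1L, as.integer(round(global_fraction * m)))
    idx[[i]] <- if (n_keep >= m) rows else rows[sample.int(m, n_keep)]
    wt[i] <- m / n_keep
  }
  lens <- lengths(idx)
  sampled <- expsets$candidates[unlist(idx)]
  sampled[, `:=`(set_id = rep(s$set_id, lens), is_treated = 0L,
                 weight = rep(wt, lens))]
  treated <- s[, .(patient_id = treated_patient_id,
                   index_date = treated_index_date, k, dt_entry, year,
                   set_id, is_treated = 1L, weight = 1)]
  out <- rbind(treated, sampled, use.names = TRUE)
  setorder(out, set_id, -is_treated, patient_id, index_date)
  setcolorder(out, c("set_id", "patient_id", "index_date", "k", "dt_entry",
                     "year", "is_treated", "weight"))
  as.data.frame(out)
}

# ---- design-matrix machinery -------------------------------------------

# a template records, per covariate, how to turn raw values into numeric
# design columns so that fit-time and predict-time encodings agree
design_template <- function(df) {
  lapply(df, function(x) {
    if (is.numeric(x) && length(unique(x[!is.na(x)])) > 2L) {
      s <- sd(x, na.rm = TRUE)
      list(type = "num", center = mean(x, na.rm = TRUE),
           scale = if (is.na(s) || s == 0) 1 else s)
    } else {
      x <- as.character(x)
      x[is.na(x)] <- "missing"
      list(type = "cat", levels = sort(unique(x)))
    }
  })
}

apply_design <- function(df, template) {
  cols <- list()
  for (nm in names(template)) {
    tp <- template[[nm]]
    x <- df[[nm]]
    if (is.null(x)) stop("covariate not found: ", nm)
    if (tp$type == "num") {
      cols[[nm]] <- (as.numeric(x) - tp$center) / tp$scale
    } else {
      x <- as.character(x)
      x[is.na(x)] <- "missing"
      for (lv in tp$levels[-1L])
        cols[[paste0(nm, "_", lv)]] <- as.numeric(x == lv)
    }
  }
  do.call(cbind, cols)
}

#' Build the stacked TCPS estimation data
#'
#' Joins stacked exposure-set rows to patient covariates and encodes the
#' design matrix of the conditional logistic model: continuous covariates are
#' standardized, categoricals (including an explicit `missing` level) are
#' one-hot encoded against a reference level, and the calendar year of the
#' index date enters as a categorical covariate. Columns without within-set
#' variation in any set (for instance calendar year under the hybrid
#' definition, which conditions on it) carry no information in the
#' conditional likelihood and are dropped, with their names recorded.
#'
#' @param rows stacked rows from [sample_within_sets()] (or all members with
#'   unit weight).
#' @param patients patient table carrying the covariate columns.
#' @param covariates character vector of patient columns to use; default all
#'   columns except identifiers and dates.
#' @param include_year include calendar year of the index date as a
#'   categorical covariate (default TRUE).
#' @param template internal: a fitted template to reuse at prediction time.
#' @return Object of class `pnu_tcps_data`: list with the design matrix `X`,
#'   `is_treated`, `weight`, `set_id`, the encoding `template`, and names of
#'   `dropped` (set-constant) columns.
#' @export
build_tcps_data <- function(rows, patients, covariates = NULL,
                            include_year = TRUE, template = NULL) {
  if (is.null(covariates))
    covariates <- setdiff(names(patients),
                          c("patient_id", "registration_date", "death_date",
                            "transfer_date"))
  raw <- merge(as.data.table(rows),
               as.data.table(patients)[, c("patient_id", covariates),
                                       with = FALSE],
               by = "patient_id", sort = FALSE)
  setorder(raw, set_id, -is_treated, patient_id, index_date)
  df <- as.data.frame(raw)[, covariates, drop = FALSE]
  if (include_year) df$cal_year <- as.character(raw$year)
  if (is.null(template)) template <- design_template(df)
  X <- apply_design(df, template)
  if (is.null(X)) X <- matrix(numeric(0), nrow(df), 0L)

  dropped <- character(0)
  if (nrow(X)) {
    # columns constant within every set are unidentified in the
    # conditional likelihood
    dx <- as.data.table(X)[, set_id := raw$set_id]
    rng <- dx[, lapply(.SD, function(v) max(v) - min(v)), by = set_id]
    informative <- vapply(rng[, !"set_id"], function(r) any(r > 0),
                          logical(1L))
    dropped <- colnames(X)[!informative]
    X <- X[, informative, drop = FALSE]
  }
  w <- if ("weight" %in% names(raw)) raw$weight else rep(1, nrow(raw))
  w[raw$is_treated == 1L] <- 1
  structure(list(X = X, is_treated = raw$is_treated, weight = w,
                 set_id = raw$set_id, template = template,
                 covariates = covariates, include_year = include_year,
                 dropped = dropped,
                 rows = as.data.frame(raw[, .(set_id, patient_id, index_date,
                                              is_treated)])),
            class = "pnu_tcps_data")
}

#' Weighted exposure-set-conditional log-likelihood
#'
#' The pseudo-log-likelihood of the TCPS model. Each exposure set `s` with a
#' treated row and at least one comparator row contributes
#' `eta_treated - log( exp(eta_treated) + sum_j w_j exp(eta_j) )` with
#' `eta = X beta`; comparator rows carry their inverse-sampling-fraction
#' weights in the denominator sum, the treated row weight 1. Sets without
#' comparator rows contribute zero. Evaluated with per-set log-sum-exp for
#' numerical stability.
#'
#' @param beta coefficient vector (length `ncol(X)`).
#' @param X numeric design matrix.
#' @param is_treated 0/1 vector, exactly one 1 per set.
#' @param weight positive weights (1 on treated rows).
#' @param set_id set identifier per row.
#' @return The scalar log-likelihood.
#' @export
tcps_loglik <- function(beta, X, is_treated, weight, set_id) {
  clogit_derivs(beta, X, is_treated, weight, set_id, order = 0L)$loglik
}

# log-likelihood, score and observed information of the weighted
# conditional-logit pseudo-likelihood, computed set-by-set via softmax
clogit_derivs <- function(beta, X, is_treated, weight, set_id, order = 2L) {
  eta <- drop(X %*% beta)
  if (any(!is.finite(eta)))
    stop("non-finite linear predictor; rescale covariate ",
         colnames(X)[which.max(apply(X, 2L, function(c) max(abs(c))))])
  sid <- match(set_id, unique(set_id))
  # sets need >= 2 rows (treated + comparator) to be informative
  n_per <- tabulate(sid)
  keep <- n_per[sid] >= 2L
  eta <- eta[keep]; w <- weight[keep]; y <- is_treated[keep]
  Xk <- X[keep, , drop = FALSE]; sidk <- match(sid[keep], unique(sid[keep]))
  if (!length(eta))
    return(list(loglik = 0, grad = rep(0, ncol(X)), hess = diag(0, ncol(X)),
                n_sets_used = 0L))
  mx <- as.vector(tapply(eta, sidk, max))
  z <- w * exp(eta - mx[sidk])
  denom <- as.vector(rowsum(z, sidk))
  ll <- sum(eta[y == 1L]) - sum(log(denom) + mx)
  out <- list(loglik = ll, n_sets_used = length(denom))
  if (order >= 1L) {
    p <- z / denom[sidk]
    out$grad <- colSums(Xk * (y - p))
    if (order >= 2L) {
      Xp <- Xk * p
      M <- rowsum(Xp, sidk)
      out$hess <- -(crossprod(Xk, Xp) - crossprod(M))
    }
  }
  out
}

#' Fit the TCPS conditional logistic model
#'
#' Maximizes the weighted exposure-set-conditional log-likelihood
#' ([tcps_loglik()]) by Newton-Raphson with step halving. The likelihood is
#' concave, so the iteration log shows a monotone non-decreasing
#' log-likelihood. Under separation (an unbounded likelihood) the fit is
#' flagged non-converged; refitting with a small ridge penalty
#' (`ridge > 0`) always returns a finite maximizer, and `fit_tcps()` falls
#' back to `ridge = 1e-6` automatically when the unpenalized Newton step
#' fails on a singular information matrix.
#'
#' @param data a `pnu_tcps_data` from [build_tcps_data()].
#' @param ridge nonnegative L2 penalty on the coefficients (default 0).
#' @param tol convergence tolerance on the max absolute score (default 1e-8).
#' @param max_iter maximum Newton iterations (default 100).
#' @return Object of class `pnu_tcps_model`: named `beta`, `converged`,
#'   `log_likelihood`, `n_sets_used`, `iterations`, the `ridge` used, the
#'   encoding `template`, and the `trace` of log-likelihood values.
#' @export
fit_tcps <- function(data, ridge = 0, tol = 1e-8, max_iter = 100L) {
  stopifnot(inherits(data, "pnu_tcps_data"))
  X <- data$X
  if (!ncol(X)) stop("no informative covariate columns to fit")
  beta <- rep(0, ncol(X))
  trace <- numeric(0)
  converged <- FALSE
  used_ridge <- ridge
  d <- clogit_derivs(beta, X, data$is_treated, data$weight, data$set_id)
  if (d$n_sets_used == 0L) stop("no informative exposure set (all empty)")
  for (it in seq_len(max_iter)) {
    pll <- d$loglik - used_ridge / 2 * sum(beta^2)
    trace <- c(trace, pll)
    g <- d$grad - used_ridge * beta
    if (max(abs(g)) < tol) {
      # under separation the score also vanishes as |beta| diverges; on the
      # standardized covariate scale genuine maximizers stay small
      converged <- used_ridge > 0 || max(abs(beta)) < 15
      break
    }
    H <- d$hess - used_ridge * diag(ncol(X))
    step <- tryCatch(solve(-H, g), error = function(e) NULL)
    if (is.null(step)) {
      if (used_ridge == 0) { # singular information: retry penalized
        used_ridge <- 1e-6
        H <- d$hess - used_ridge * diag(ncol(X))
        step <- solve(-H, g)
      } else stop("information matrix singular despite ridge penalty")
    }
    # step halving keeps the penalized log-likelihood non-decreasing
    for (h in 0:30) {
      beta_new <- beta + step / 2^h
      d_new <- clogit_derivs(beta_new, X, data$is_treated, data$weight,
                             data$set_id)
      if (d_new$loglik - used_ridge / 2 * sum(beta_new^2) >= pll - 1e-12)
        break
    }
    beta <- beta_new
    d <- d_new
    # runaway coefficients signal separation when unpenalized
    if (used_ridge == 0 && max(abs(beta)) > 1e3) break
  }
  names(beta) <- colnames(X)
  structure(list(beta = beta, converged = converged,
                 log_likelihood = d$loglik, n_sets_used = d$n_sets_used,
                 iterations = length(trace), ridge = used_ridge,
                 template = data$template, covariates = data$covariates,
                 include_year = data$include_year, dropped = data$dropped,
                 trace = trace),
            class = "pnu_tcps_model")
}

#' @export
print.pnu_tcps_model <- function(x, ...) {
  cat("<pnu_tcps_model>", length(x$beta), "coefficients,",
      x$n_sets_used, "informative sets\n")
  cat("  converged:", x$converged, " logLik:",
      format(x$log_likelihood, digits = 6),
      " iterations:", x$iterations, "\n")
  if (length(x$dropped))
    cat("  dropped (constant within sets):",
        paste(x$dropped, collapse = ", "), "\n")
  print(round(x$beta, 4))
  invisible(x)
}

#' Predict time-conditional propensity scores for all set members
#'
#' Applies the fitted TCPS model to every member of every exposure set —
#' sampled or not — returning `plogis(x beta)` per member. Scores are used
#' for the within-set positivity check and nearest-score matching, where only
#' score differences within a set matter, so the omitted set-level intercept
#' is immaterial. The score depends only on patient covariates and the index
#' calendar year, so each unique (patient, year) combination is scored once;
#' covariate columns dropped at fit time (constant within every set) take
#' coefficient zero.
#'
#' @param model a `pnu_tcps_model`.
#' @param expsets the [build_exposure_sets()] result to score.
#' @param patients patient table with the covariate columns used at fit time.
#' @return Object of class `pnu_tcps_scores`: the `expsets` object plus
#'   `candidate_score` (aligned to `expsets$candidates` rows) and
#'   `treated_score` (aligned to `expsets$sets` rows), all in (0, 1).
#'   `scores_members()` materializes the scored member table.
#' @export
predict_tcps <- function(model, expsets, patients) {
  stopifnot(inherits(model, "pnu_tcps_model"),
            inherits(expsets, "pnu_exposure_sets"))
  score_of <- function(pid, yr) {
    u <- data.table(patient_id = pid, year = yr)
    uniq <- unique(u)
    uniq <- merge(uniq,
                  as.data.table(patients)[, c("patient_id",
                                              model$covariates),
                                          with = FALSE],
                  by = "patient_id", sort = FALSE)
    dfo <- as.data.frame(uniq)[, model$covariates, drop = FALSE]
    if (model$include_year) dfo$cal_year <- as.character(uniq$year)
    X <- apply_design(dfo, model$template)
    if (is.null(X)) X <- matrix(numeric(0), nrow(dfo), 0L)
    beta_full <- setNames(rep(0, ncol(X)), colnames(X))
    beta_full[names(model$beta)] <- model$beta
    uniq[, score := plogis(drop(X %*% beta_full))]
    u[uniq, on = .(patient_id, year), score := i.score]
    u$score
  }
  structure(list(
    expsets = expsets,
    candidate_score = if (nrow(expsets$candidates))
      score_of(expsets$candidates$patient_id, expsets$candidates$year)
    else numeric(0),
    treated_score = score_of(expsets$sets$treated_patient_id,
                             expsets$sets$year)
  ), class = "pnu_tcps_scores")
}

#' @rdname predict_tcps
#' @param scores a `pnu_tcps_scores` object.
#' @export
scores_members <- function(scores) {
  stopifnot(inherits(scores, "pnu_tcps_scores"))
  m <- as.data.table(expsets_members(scores$expsets))
  cs <- data.table(scores$expsets$candidates[, .(patient_id, year)],
                   score = scores$candidate_score)
  cs <- unique(cs)
  m[cs, on = .(patient_id, year), score := i.score]
  ts <- data.table(scores$expsets$sets[, .(set_id)],
                   score = scores$treated_score)
  m[is_treated == 1L, score := ts$score[match(set_id, ts$set_id)]]
  as.data.frame(m)
}
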