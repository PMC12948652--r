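# direct construction of estimation data, bypassing the design-matrix
# builder, for likelihood-level tests
raw_tcps_data <- function(X, is_treated, weight, set_id) {
  structure(list(X = X, is_treated = as.integer(is_treated),
                 weight = weight, set_id = set_id, template = NULL,
                 covariates = NULL, include_year = FALSE,
                 dropped = character(0)),
            class = "pnu_tcps_data")
}

test_that("within-set sampling fractions and weights multiply to one", {
  sets <- set_row(1L, 999L)
  big <- cand_row(seq_len(1000L) + 1000L)
  es <- manual_expsets(sets, list(big))
  st <- sample_within_sets(es, target_per_set = 50, seed = 1)
  smp <- st[st$is_treated == 0L, ]
  expect_equal(nrow(smp), 50L)
  expect_true(all(smp$weight == 20)) # 1 / f = 1000 / 50
  expect_equal(st$weight[st$is_treated == 1L], 1)

  # small set: capped fraction keeps everyone at weight 1
  es2 <- manual_expsets(sets, list(cand_row(seq_len(10L) + 1000L)))
  st2 <- sample_within_sets(es2, target_per_set = 50, seed = 1)
  expect_equal(sum(st2$is_treated == 0L), 10L)
  expect_true(all(st2$weight == 1))

  # reproducibility
  expect_identical(sample_within_sets(es, 50, seed = 7),
                   sample_within_sets(es, 50, seed = 7))
})

test_that("forcing the fraction to one keeps every candidate once, weight 1", {
  fx <- small_sim()
  es <- build_exposure_sets(fx$cohort, fx$sim$prescriptions,
                            exposure_definition("hybrid", 30))
  st <- sample_within_sets(es, target_per_set = max(es$sets$n_candidates),
                           seed = 1)
  expect_true(all(st$weight == 1))
  m <- expsets_members(es)
  expect_equal(nrow(st), nrow(m))
  expect_setequal(paste(st$set_id, st$patient_id, st$index_date),
                  paste(m$set_id, m$patient_id, m$index_date))
})

test_that("conditional log-likelihood matches closed forms on tiny sets", {
  X <- matrix(c(1, 0), ncol = 1)
  d <- raw_tcps_data(X, c(1L, 0L), c(1, 1), c(1L, 1L))
  expect_equal(tcps_loglik(0, d$X, d$is_treated, d$weight, d$set_id),
               log(1 / 2))
  d2 <- raw_tcps_data(X, c(1L, 0L), c(1, 2), c(1L, 1L))
  expect_equal(tcps_loglik(0, d2$X, d2$is_treated, d2$weight, d2$set_id),
               log(1 / 3))
})

test_that("likelihood and gradient match brute-force enumeration", {
  for (r in 1:25) {
    set.seed(900 + r)
    n_sets <- sample(1:5, 1L)
    rows <- do.call(rbind, lapply(seq_len(n_sets), function(s) {
      m <- sample(2:5, 1L)
      data.frame(set = s, y = as.integer(seq_len(m) == 1L),
                 w = c(1, round(runif(m - 1L, 0.5, 4), 2)))
    }))
    p <- sample(1:3, 1L)
    X <- matrix(rnorm(nrow(rows) * p), ncol = p)
    beta <- rnorm(p)
    expect_equal(
      tcps_loglik(beta, X, rows$y, rows$w, rows$set),
      oracle_clogit_loglik(beta, X, rows$y, rows$w, rows$set),
      tolerance = 1e-10)
    g <- pnucohort:::clogit_derivs(beta, X, rows$y, rows$w, rows$set)$grad
    g_num <- num_grad(function(b)
      oracle_clogit_loglik(b, X, rows$y, rows$w, rows$set), beta)
    expect_equal(g, g_num, tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("the MLE agrees with a one-dimensional grid search", {
  set.seed(321)
  rows <- do.call(rbind, lapply(1:60, function(s) {
    m <- 4L
    x <- rbinom(m, 1L, 0.5)
    p <- exp(0.9 * x); p <- p / sum(p)
    data.frame(set = s, x = x,
               y = as.integer(seq_len(m) == sample(m, 1L, prob = p)),
               w = 1)
  }))
  X <- matrix(rows$x, ncol = 1)
  d <- raw_tcps_data(X, rows$y, rows$w, rows$set)
  fit <- fit_tcps(d)
  grid <- seq(-3, 3, by = 1e-4)
  ll <- vapply(grid, function(b)
    oracle_clogit_loglik(b, X, rows$y, rows$w, rows$set), numeric(1L))
  expect_true(fit$converged)
  expect_equal(unname(fit$beta), grid[which.max(ll)], tolerance = 1e-4)
})

test_that("uninformative covariates give a zero coefficient", {
  # treated and comparators share identical covariate values in every set
  rows <- do.call(rbind, lapply(1:20, function(s)
    data.frame(set = s, x = s %% 3, y = c(1L, 0L, 0L), w = 1)))
  X <- matrix(rows$x, ncol = 1)
  d <- raw_tcps_data(X, rows$y, rows$w, rows$set)
  fit <- fit_tcps(d)
  expect_equal(unname(fit$beta), 0, tolerance = 1e-8)
})

test_that("separation is flagged, and a ridge penalty restores a finite fit", {
  # treated always has x = 1, comparators x = 0: likelihood unbounded
  rows <- do.call(rbind, lapply(1:15, function(s)
    data.frame(set = s, x = c(1, 0, 0), y = c(1L, 0L, 0L), w = 1)))
  X <- matrix(rows$x, ncol = 1)
  d <- raw_tcps_data(X, rows$y, rows$w, rows$set)
  fit <- fit_tcps(d)
  expect_false(fit$converged)
  fitr <- fit_tcps(d, ridge = 1e-2)
  expect_true(fitr$converged)
  expect_true(is.finite(fitr$beta))
})

test_that("the log-likelihood is concave (negative semi-definite Hessian)", {
  set.seed(42)
  rows <- do.call(rbind, lapply(1:10, function(s) {
    m <- sample(2:5, 1L)
    data.frame(set = s, y = as.integer(seq_len(m) == 1L),
               w = runif(m, 0.5, 3))
  }))
  X <- matrix(rnorm(nrow(rows) * 2), ncol = 2)
  for (r in 1:10) {
    H <- pnucohort:::clogit_derivs(rnorm(2), X, rows$y, rows$w,
                                   rows$set)$hess
    expect_lte(max(eigen(H, symmetric = TRUE)$values), 1e-8)
  }
})

test_that("weighted fit recovers the assignment model on simulated sets", {
  set.seed(2024)
  beta_true <- c(0.8, -0.5)
  rows <- do.call(rbind, lapply(1:2000, function(s) {
    m <- 5L
    X <- cbind(rnorm(m), rbinom(m, 1L, 0.4))
    p <- exp(X %*% beta_true); p <- p / sum(p)
    data.frame(set = s, x1 = X[, 1], x2 = X[, 2],
               y = as.integer(seq_len(m) == sample(m, 1L, prob = p)), w = 1)
  }))
  X <- as.matrix(rows[, c("x1", "x2")])
  d <- raw_tcps_data(X, rows$y, rows$w, rows$set)
  fit <- fit_tcps(d)
  H <- pnucohort:::clogit_derivs(fit$beta, X, rows$y, rows$w, rows$set)$hess
  se <- sqrt(diag(solve(-H)))
  expect_true(all(abs(fit$beta - beta_true) < 3 * se))
  # independent cross-check against the survival package's conditional fit
  withr::local_package("survival")
  cl <- survival::clogit(y ~ x1 + x2 + strata(set), data = rows)
  expect_equal(unname(fit$beta), unname(coef(cl)), tolerance = 1e-6)
})

test_that("sampling-consistent: fraction one reproduces the full-data fit", {
  fx <- small_sim()
  es <- build_exposure_sets(fx$cohort, fx$sim$prescriptions,
                            exposure_definition("hybrid", 30))
  st <- sample_within_sets(es, target_per_set = max(es$sets$n_candidates),
                           seed = 3)
  full <- expsets_members(es) # no weight column: unit weights
  fit_s <- fit_tcps(build_tcps_data(st, fx$sim$patients))
  fit_f <- fit_tcps(build_tcps_data(full, fx$sim$patients))
  expect_identical(fit_s$beta, fit_f$beta)
})

test_that("scores are logistic in the linear predictor and saturate safely", {
  sets <- set_row(1L, 999L)
  es <- manual_expsets(sets, list(cand_row(1:3)))
  pats <- fix_patients(c(999L, 1:3))
  pats$x <- c(1, 0, 0, 1) # two-level covariate, dummy column x_1
  st <- sample_within_sets(es, 10, seed = 1)
  d <- build_tcps_data(st, pats, covariates = "x", include_year = FALSE)
  make_model <- function(beta)
    structure(list(beta = setNames(beta, "x_1"), converged = TRUE,
                   template = d$template, covariates = "x",
                   include_year = FALSE, dropped = character(0)),
              class = "pnu_tcps_model")
  # zero coefficients: every score is exactly one half
  sc0 <- predict_tcps(make_model(0), es, pats)
  expect_true(all(scores_members(sc0)$score == 0.5))
  # finite coefficient: plogis of the dummy
  sc <- predict_tcps(make_model(0.5), es, pats)
  expect_equal(sc$treated_score, plogis(0.5))
  expect_equal(sc$candidate_score, plogis(0.5 * c(0, 0, 1)))
  # a huge linear predictor saturates to 1 without overflow
  sc2 <- predict_tcps(make_model(1e4), es, pats)
  expect_equal(sc2$treated_score, 1)
  expect_equal(sc2$candidate_score, c(0.5, 0.5, 1))
  expect_true(all(is.finite(sc2$candidate_score)))
})

test_that("predicted scores equal scores computed from the stacked rows", {
  fx <- small_sim()
  es <- build_exposure_sets(fx$cohort, fx$sim$prescriptions,
                            exposure_definition("hybrid", 30))
  st <- sample_within_sets(es, 25, seed = 9)
  d <- build_tcps_data(st, fx$sim$patients)
  model <- fit_tcps(d)
  sc <- scores_members(predict_tcps(model, es, fx$sim$patients))
  # recompute directly from the stacked design
  eta <- drop(d$X %*% model$beta)
  direct <- data.frame(set_id = d$rows$set_id,
                       patient_id = d$rows$patient_id,
                       index_date = d$rows$index_date,
                       score = plogis(eta))
  joined <- merge(direct, sc, by = c("set_id", "patient_id", "index_date"))
  expect_equal(nrow(joined), nrow(direct))
  expect_equal(joined$score.x, joined$score.y, tolerance = 1e-12)
})
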