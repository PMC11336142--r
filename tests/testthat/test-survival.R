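# survival & adversity: Cox contracts vs a hand-written Efron oracle,
# counting-process invariances, adversity scoring, delta-age mixed models

# independent oracle: Efron-approximation partial log-likelihood for a
# single covariate on (start, stop] counting-process records
efron_loglik <- function(beta, rec, cov) {
  times <- sort(unique(rec$stop_age[rec$event == 1]))
  ll <- 0
  for (tm in times) {
    dead <- which(rec$event == 1 & abs(rec$stop_age - tm) < 1e-12)
    risk <- which(rec$start_age < tm & rec$stop_age >= tm)
    d <- length(dead)
    eta <- beta * rec[[cov]]
    rs <- sum(exp(eta[risk]))
    ds <- sum(exp(eta[dead]))
    ll <- ll + sum(eta[dead])
    for (l in seq_len(d) - 1) ll <- ll - log(rs - (l / d) * ds)
  }
  ll
}

cox_fixture <- function() {
  # 8 observations, tied event times, binary covariate
  data.frame(
    individual_id = sprintf("i%d", 1:8),
    start_age = c(4, 4, 4, 4, 5, 5, 4, 4),
    stop_age = c(6, 6, 7, 8, 8, 9, 10, 10),
    event = c(1, 1, 0, 1, 1, 1, 0, 1),
    x = c(1, 1, 0, 1, 0, 0, 1, 0))
}

test_that("fit_cox matches grid maximization of the Efron partial likelihood", {
  rec <- cox_fixture()
  fit <- fit_cox(rec, "x")
  oracle <- stats::optimize(function(b) efron_loglik(b, rec, "x"),
                            c(-5, 5), maximum = TRUE)$maximum
  expect_equal(fit$results$coefficient, oracle, tolerance = 1e-4)
  expect_equal(fit$results$hazard_ratio, exp(fit$results$coefficient))
  expect_true(fit$results$ci_low <= fit$results$hazard_ratio &&
                fit$results$hazard_ratio <= fit$results$ci_high)
  expect_equal(fit$n_events, 6)
})

test_that("splitting an interval at an event-free time leaves the fit unchanged", {
  rec <- cox_fixture()
  fit0 <- fit_cox(rec, "x")
  # split individual 7's (4, 10] interval at the event-free time 6.5
  r7 <- rec[7, ]
  a <- r7; a$stop_age <- 6.5; a$event <- 0
  b <- r7; b$start_age <- 6.5
  rec2 <- rbind(rec[-7, ], a, b)
  fit2 <- fit_cox(rec2, "x")
  expect_equal(fit2$results$coefficient, fit0$results$coefficient,
               tolerance = 1e-8)
})

test_that("Cox coefficient is invariant to centering and scales under rescaling", {
  rec <- cox_fixture()
  rec$z <- c(0.3, 1.2, -0.5, 2.0, 0.1, -1.0, 0.8, -0.2)
  f0 <- fit_cox(rec, "z")
  rec$zc <- rec$z - mean(rec$z)
  expect_equal(fit_cox(rec, "zc")$results$coefficient,
               f0$results$coefficient, tolerance = 1e-8)
  rec$zs <- rec$z * 4
  expect_equal(fit_cox(rec, "zs")$results$hazard_ratio,
               f0$results$hazard_ratio^(1 / 4), tolerance = 1e-6)
})

test_that("cluster duplication keeps the coefficient, sandwich SEs diverge", {
  set.seed(3)
  n <- 120
  rec <- data.frame(individual_id = sprintf("i%03d", 1:n),
                    start_age = 4,
                    stop_age = 4 + rexp(n, 0.1) + (1:n) * 1e-6,  # unique times
                    event = rbinom(n, 1, 0.7),
                    z = rnorm(n))
  dup <- rbind(rec, rec)
  fd_naive <- fit_cox(dup, "z", cluster = NULL, ties = "breslow")
  fd_rob <- fit_cox(dup, "z", cluster = "individual_id", ties = "breslow")
  f0b <- fit_cox(rec, "z", cluster = NULL, ties = "breslow")
  f0r <- fit_cox(rec, "z", cluster = "individual_id", ties = "breslow")
  expect_equal(fd_naive$results$coefficient, f0b$results$coefficient,
               tolerance = 1e-6)
  # naive SE shrinks ~ 1/sqrt(2); the clustered sandwich recovers the
  # original robust SE exactly (scores double, information doubles)
  expect_equal(fd_naive$results$se, f0b$results$se / sqrt(2),
               tolerance = 0.02)
  expect_equal(fd_rob$results$se, f0r$results$se, tolerance = 0.02)
  expect_gt(fd_rob$results$se, fd_naive$results$se)
})

test_that("fit_cox rejects degenerate inputs", {
  rec <- cox_fixture()
  rec0 <- rec; rec0$event <- 0
  expect_error(fit_cox(rec0, "x"), "no events")
  recc <- rec; recc$x <- 1
  expect_error(fit_cox(recc, "x"), "non-identifiable")
})

test_that("lifetime records honor delayed entry and vital integrity", {
  lt <- data.frame(individual_id = c("A", "B"),
                   lifetime_relative_age = c(0.5, -0.2))
  vit <- data.frame(individual_id = c("A", "B"), entry_age = 4,
                    end_age = c(12, 20), event = c(1, 0))
  fo <- data.frame(individual_id = c("A", "B"), age = c(6, 4))
  rec <- build_lifetime_records(lt, vit, first_observed = fo)
  expect_equal(rec$start_age, c(6, 4))   # delayed entry at first observation
  expect_equal(rec$event, c(1, 0))
  expect_error(build_lifetime_records(
    data.frame(individual_id = "Z", lifetime_relative_age = 0), vit),
    "no vital record")
})

test_that("annual records assign deaths to retained final years only", {
  preds <- data.frame(individual_id = "A", year_index = 0:6,
                      known_age = 4:10, relative_age = rnorm(7))
  vit <- data.frame(individual_id = "A", entry_age = 4, end_age = 10.6,
                    event = 1)
  rec <- build_annual_records(preds, vit)
  expect_equal(nrow(rec), 7)
  expect_equal(sum(rec$event), 1)
  expect_equal(rec$event[7], 1)
  expect_true(all(rec$stop_age - rec$start_age <= 1 + 1e-12))
  expect_equal(rec$stop_age[7], 10.6)

  # death year filtered out (no prediction for it) -> no event contributed
  preds2 <- preds[1:6, ]   # final year dropped by the <60-day filter
  rec2 <- build_annual_records(preds2, vit)
  expect_equal(sum(rec2$event), 0)
  expect_equal(nrow(rec2), 6)
})

test_that("cumulative adversity scoring follows the quartile rules", {
  set.seed(12)
  n <- 200
  prof <- data.frame(individual_id = sprintf("i%03d", 1:n),
                     maternal_death = rbinom(n, 1, 0.2),
                     close_sibling = rbinom(n, 1, 0.2),
                     drought = rbinom(n, 1, 0.2),
                     maternal_sci = rnorm(n),
                     maternal_rank = runif(n),
                     group_size = rnorm(n, 25, 6))
  out <- cumulative_adversity(prof)
  pr <- out$profiles
  expect_equal(pr$cumulative_index,
               rowSums(pr[, paste0("flag_", c("maternal_death",
                                              "close_sibling", "drought",
                                              "maternal_sci", "maternal_rank",
                                              "group_size"))]),
               ignore_attr = TRUE)
  # continuous sources flag ~25% each (inclusive thresholds)
  expect_equal(mean(pr$flag_maternal_sci), 0.25, tolerance = 0.02)
  expect_equal(mean(pr$flag_group_size), 0.25, tolerance = 0.02)

  # boundary: value exactly at the quartile is flagged adverse
  qgs <- quantile(prof$group_size, 0.75)
  prof2 <- prof
  prof2$group_size[1] <- qgs
  out2 <- cumulative_adversity(prof2, population = prof)
  expect_true(out2$profiles$flag_group_size[1])

  # hand case: two binary sources only -> index 2
  one <- prof[1, ]
  one$maternal_death <- 1; one$close_sibling <- 0; one$drought <- 1
  one$maternal_sci <- 10; one$maternal_rank <- 0.99; one$group_size <- -10
  idx <- cumulative_adversity(one, population = prof)$profiles$cumulative_index
  expect_equal(idx, 2)
  # all benign -> 0
  benign <- one; benign$maternal_death <- 0; benign$drought <- 0
  expect_equal(cumulative_adversity(benign,
                                    population = prof)$profiles$cumulative_index, 0)

  # missing source -> excluded with log entry
  prof3 <- prof
  prof3$drought[5] <- NA
  out3 <- cumulative_adversity(prof3)
  expect_equal(out3$excluded, prof3$individual_id[5])
  expect_equal(nrow(out3$profiles), n - 1)
})

test_that("delta-age mixed model recovers an injected adversity effect", {
  set.seed(21)
  n_ind <- 150; years <- 6
  idx_ind <- rep(1:n_ind, each = years)
  index <- sample(0:4, n_ind, replace = TRUE)
  frailty <- rnorm(n_ind, 0, 0.8) + 0.3 * index
  preds <- data.frame(individual_id = sprintf("i%03d", idx_ind),
                      year_index = rep(0:(years - 1), n_ind),
                      known_age = rep(4:(3 + years), n_ind))
  preds$delta_age <- frailty[idx_ind] + rnorm(n_ind * years, 0, 0.6)
  profiles <- data.frame(individual_id = sprintf("i%03d", 1:n_ind),
                         cumulative_index = index,
                         maternal_death = rbinom(n_ind, 1, 0.2),
                         close_sibling = rbinom(n_ind, 1, 0.2),
                         drought = rbinom(n_ind, 1, 0.2),
                         maternal_sci = rnorm(n_ind),
                         maternal_rank = runif(n_ind),
                         group_size = rnorm(n_ind, 25, 5))
  conditions <- data.frame(individual_id = preds$individual_id,
                           year_index = preds$year_index,
                           rank_prop = runif(n_ind * years),
                           group_size = rnorm(n_ind * years, 25, 5),
                           rain_anomaly = rnorm(n_ind * years))
  fit <- fit_delta_age_lmm(preds, profiles, conditions, mode = "cumulative")
  b <- fit$coefficients
  est <- b$estimate[b$term == "cumulative_index"]
  se <- b$se[b$term == "cumulative_index"]
  expect_lt(abs(est - 0.3), 2.5 * se)
  expect_lt(b$p_value[b$term == "cumulative_index"], 0.05)
  expect_true("known_age" %in% b$term)
  expect_gt(fit$random_intercept_variance, 0)

  # multivariable mode exposes the six sources
  fitm <- fit_delta_age_lmm(preds, profiles, conditions,
                            mode = "multivariable")
  expect_true(all(c("maternal_death", "drought") %in%
                    fitm$coefficients$term))

  # constant response -> all covariate effects (numerically) zero
  preds0 <- preds; preds0$delta_age <- 1
  fit0 <- suppressWarnings(fit_delta_age_lmm(preds0, profiles, conditions))
  b0 <- fit0$coefficients
  expect_lt(max(abs(b0$estimate[b0$term != "(Intercept)"])), 1e-8)
})

test_that("adversity confounding attenuates the relative-age hazard ratio", {
  set.seed(31)
  n <- 400
  index <- sample(0:4, n, replace = TRUE)
  # full confounding: frailty is exactly proportional to the index
  frailty <- 0.8 * index
  rec <- data.frame(individual_id = sprintf("i%03d", 1:n), start_age = 4,
                    stop_age = NA_real_, event = 1L,
                    lifetime_relative_age = frailty + rnorm(n, 0, 0.3))
  rec$stop_age <- 4 + rexp(n, 0.093 * exp(0.4 * frailty))
  profiles <- data.frame(individual_id = rec$individual_id,
                         cumulative_index = index)
  out <- fit_cox_with_adversity(rec, profiles)
  expect_lt(out$attenuation, 0.8)  # HR pulled toward 1 by the confounder
  expect_gt(out$without$results$hazard_ratio[1], 1)

  # independence: adversity unrelated to frailty -> no attenuation
  frailty2 <- rnorm(n, 0, 1)
  rec2 <- rec
  rec2$lifetime_relative_age <- frailty2 + rnorm(n, 0, 0.3)
  rec2$stop_age <- 4 + rexp(n, 0.093 * exp(0.4 * frailty2))
  out2 <- fit_cox_with_adversity(rec2, profiles)
  expect_equal(out2$attenuation, 1, tolerance = 0.15)

  # constant index -> non-identifiable
  prof_const <- data.frame(individual_id = rec$individual_id,
                           cumulative_index = 2)
  expect_error(fit_cox_with_adversity(rec, prof_const), "non-identifiable")
})
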