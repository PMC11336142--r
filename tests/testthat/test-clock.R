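# random-forest clock: forest behavior, metrics, relative age, repeatability

sim_features <- function(n, p, b = 0.1, noise = 0.5, seed = 1) {
  set.seed(seed)
  age <- runif(n, 4, 27)
  X <- vapply(seq_len(p), function(j) b * age + rnorm(n, 0, noise),
              numeric(n))
  colnames(X) <- sprintf("t%02d", seq_len(p))
  list(X = X, age = age)
}

test_that("forest is deterministic and learns strong age signal", {
  d <- sim_features(600, 10)
  f1 <- rf_regression(d$X, d$age, ntree = 60, seed = 4)
  f2 <- rf_regression(d$X, d$age, ntree = 60, seed = 4)
  expect_identical(f1$oob, f2$oob)
  expect_identical(predict(f1, d$X), predict(f2, d$X))
  ok <- !is.na(f1$oob)
  expect_gt(cor(f1$oob[ok], d$age[ok])^2, 0.9)

  # pure-noise features: out-of-bag R^2 near zero
  set.seed(8)
  Xn <- matrix(rnorm(600 * 10), 600, 10,
               dimnames = list(NULL, sprintf("t%02d", 1:10)))
  fn <- rf_regression(Xn, d$age, ntree = 100, seed = 4)
  ok <- !is.na(fn$oob)
  expect_lt(cor(fn$oob[ok], d$age[ok])^2, 0.05)

  expect_error(rf_regression(cbind(x = c(1, NA)), c(1, 2)), "missing cells")
})

fake_sets <- function(n_ind = 40, years = 5, m = 2, n_splits = 3, noise = 0.3,
                      seed = 2) {
  set.seed(seed)
  n <- n_ind * years
  rec <- data.frame(individual_id = rep(sprintf("I%03d", 1:n_ind),
                                        each = years),
                    year_index = rep(0:(years - 1), n_ind),
                    age_start = rep(4:(3 + years), n_ind) +
                      rep(rnorm(n_ind, 0, 2), each = years))
  rec$age_start <- pmax(4, rec$age_start)
  for (j in 1:6) rec[[sprintf("t%02d", j)]] <-
    0.2 * rec$age_start + rnorm(n, 0, noise)
  fold <- rep_len(0:(n_splits - 1), n)
  sets <- list()
  for (s in 0:(n_splits - 1)) for (im in 0:(m - 1))
    sets[[length(sets) + 1]] <- list(
      split_index = s, imputation_index = im,
      train_table = rec[fold != s, ], test_table = rec[fold == s, ])
  sets
}

test_that("mtry tuning returns grid members deterministically", {
  sets <- fake_sets()
  feats <- sprintf("t%02d", 1:6)
  expect_equal(tune_mtry(sets[1:2], feats, grid = 3, ntree = 30, seed = 1), 3)
  m1 <- tune_mtry(sets[1:2], feats, grid = c(1, 3, 6), ntree = 30, seed = 1)
  m2 <- tune_mtry(sets[1:2], feats, grid = c(1, 3, 6), ntree = 30, seed = 1)
  expect_identical(m1, m2)
  expect_true(m1 %in% c(1, 3, 6))
  expect_error(tune_mtry(sets[1:2], feats, grid = integer()), "empty")
})

test_that("predict_panel averages imputations and covers every record", {
  sets <- fake_sets(m = 2, n_splits = 3)
  feats <- sprintf("t%02d", 1:6)
  models <- lapply(sets, train_clock, features = feats, mtry = 2,
                   ntree = 40, seed = 5)
  preds <- predict_panel(models, sets)
  n_records <- nrow(sets[[1]]$train_table) + nrow(sets[[1]]$test_table)
  expect_equal(nrow(preds), n_records)
  expect_true(all(is.finite(preds$predicted_age)))
  expect_equal(preds$delta_age, preds$predicted_age - preds$known_age)

  # identical imputations (same tables) -> mean equals a single prediction
  one <- predict_panel(models[c(1, 1)], sets[c(1, 1)])
  tt <- sets[[1]]$test_table
  single <- data.frame(individual_id = tt$individual_id,
                       year_index = tt$year_index,
                       single = predict(models[[1]]$forest,
                                        as.matrix(tt[, feats])))
  cmp <- merge(one, single)
  expect_equal(cmp$predicted_age, cmp$single, tolerance = 1e-12)

  # misaligned models and sets are rejected
  expect_error(predict_panel(models[c(2, 1)], sets[c(1, 2)]),
               "misaligned")
})

test_that("clock metrics match hand-computed values", {
  id3 <- data.frame(individual_id = c("a", "b", "c"), year_index = 0L,
                    known_age = c(5, 10, 15), predicted_age = c(6, 11, 12))
  id3$delta_age <- id3$predicted_age - id3$known_age

  m <- clock_metrics(id3)
  # hand OLS: cov = 15, var(known) = 25 -> slope 0.6;
  # var(pred) = 31/3; r^2 = 15^2 / (25 * 31/3) = 27/31
  expect_equal(m$slope_pred_vs_known, 0.6, tolerance = 1e-12)
  expect_equal(m$r_squared, 27 / 31, tolerance = 1e-12)
  expect_equal(m$median_abs_error, 1.0)

  # identity and affine-compression cases
  ident <- data.frame(individual_id = letters[1:4], year_index = 0L,
                      known_age = c(5, 8, 11, 14),
                      predicted_age = c(5, 8, 11, 14))
  mi <- clock_metrics(ident)
  expect_equal(mi$r_squared, 1)
  expect_equal(mi$median_abs_error, 0)
  expect_equal(mi$slope_pred_vs_known, 1)

  aff <- ident
  aff$predicted_age <- 0.5 * aff$known_age + 6
  ma <- clock_metrics(aff)
  expect_equal(ma$r_squared, 1)
  expect_equal(ma$slope_pred_vs_known, 0.5)

  expect_error(clock_metrics(ident[1:2, ]), "at least 3")
  same <- ident; same$known_age <- 7
  expect_error(clock_metrics(same), "zero variance")
})

test_that("relative age is the pooled OLS residual with its identities", {
  d <- data.frame(individual_id = c("a", "b", "c"), year_index = 0L,
                  known_age = c(5, 10, 15), predicted_age = c(6, 11, 12))
  d$delta_age <- d$predicted_age - d$known_age
  rel <- relative_age(d)
  expect_equal(rel$preds$relative_age, c(-2 / 3, 4 / 3, -2 / 3),
               tolerance = 1e-10)
  expect_equal(rel$slope, 0.6)
  expect_equal(rel$intercept, 29 / 3 - 6, tolerance = 1e-10)

  # OLS residual identities + the delta/relative affine relation
  set.seed(6)
  d2 <- data.frame(individual_id = rep(letters[1:10], each = 4),
                   year_index = rep(0:3, 10),
                   known_age = runif(40, 4, 20))
  d2$predicted_age <- 3 + 0.7 * d2$known_age + rnorm(40)
  d2$delta_age <- d2$predicted_age - d2$known_age
  r2 <- relative_age(d2)
  expect_equal(sum(r2$preds$relative_age), 0, tolerance = 1e-10)
  expect_equal(cor(r2$preds$relative_age, r2$preds$known_age), 0,
               tolerance = 1e-10)
  expect_equal(r2$preds$relative_age,
               r2$preds$delta_age -
                 (r2$intercept + (r2$slope - 1) * r2$preds$known_age),
               tolerance = 1e-10)
  # lifetime means aggregate per individual
  expect_equal(nrow(r2$lifetime), 10)
  expect_equal(r2$lifetime$lifetime_relative_age[1],
               mean(r2$preds$relative_age[r2$preds$individual_id == "a"]))
})

test_that("repeatability matches the one-way ANOVA ICC closed form", {
  # balanced two-individual fixture {(1, 1.1), (2, 2.1)}
  d <- data.frame(individual_id = c("a", "a", "b", "b"),
                  relative_age = c(1, 1.1, 2, 2.1))
  # closed-form oracle: k = 2; MSB = 1, MSW = 0.005;
  # sigma2_b = (MSB - MSW)/k, ICC = sigma2_b / (sigma2_b + MSW)
  msb <- 2 * sum((c(1.05, 2.05) - 1.55)^2) / 1
  msw <- sum(c(-0.05, 0.05, -0.05, 0.05)^2) / 2
  icc <- ((msb - msw) / 2) / ((msb - msw) / 2 + msw)
  expect_equal(repeatability(d), icc, tolerance = 1e-6)

  # strong structure -> near 1; iid noise -> near 0
  strong <- data.frame(individual_id = rep(letters[1:6], each = 3),
                       relative_age = rep(1:6, each = 3) +
                         rnorm(18, 0, 1e-4))
  expect_gt(suppressWarnings(repeatability(strong)), 0.999)
  set.seed(9)
  flat <- data.frame(individual_id = rep(sprintf("i%03d", 1:200), each = 5),
                     relative_age = rnorm(1000))
  expect_lt(repeatability(flat), 0.05)

  expect_error(repeatability(data.frame(individual_id = c("a", "b"),
                                        relative_age = c(1, 2))),
               "undefined")
})
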