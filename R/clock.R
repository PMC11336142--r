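set_features <- function(set, features) {
  as.matrix(set[, features, drop = FALSE])
}

# standardize a train/test pair with training-partition statistics
standardize_pair <- function(train_table, test_table, registry,
                             scope = c("train", "global")) {
  scope <- match.arg(scope)
  kinds <- registry_kinds(registry)
  cont <- names(kinds)[kinds == "continuous"]
  src <- if (scope == "global") rbind(train_table[cont], test_table[cont])
         else train_table[cont]
  loc <- vapply(src, mean, 0)
  sc <- vapply(src, stats::sd, 0)
  sc[!is.finite(sc) | sc <= 0] <- 1
  for (cn in cont) {
    train_table[[cn]] <- (train_table[[cn]] - loc[[cn]]) / sc[[cn]]
    test_table[[cn]] <- (test_table[[cn]] - loc[[cn]]) / sc[[cn]]
  }
  list(train = train_table, test = test_table)
}

#' Tune the forest mtry parameter
#'
#' Fits one forest per grid value on each supplied training table and
#' returns the grid value whose mean out-of-bag R^2 (squared correlation of
#' OOB-predicted and known age) is largest; ties break toward the smaller
#' value. Deterministic per seed.
#'
#' @param train_sets List of imputed sets (their `train_table`s are used).
#' @param features Character vector of feature columns.
#' @param grid Integer candidate mtry values.
#' @param ntree Trees per tuning forest.
#' @param seed Integer seed.
#' @return The selected mtry (integer).
#' @export
tune_mtry <- function(train_sets, features, grid, ntree = 500L, seed = 1L) {
  if (!length(grid)) stop("config error: empty mtry grid")
  grid <- sort(unique(as.integer(grid)))
  r2 <- vapply(grid, function(mt) {
    mean(vapply(seq_along(train_sets), function(i) {
      st <- train_sets[[i]]
      fit <- rf_regression(set_features(st$train_table, features),
                           st$train_table$age_start, ntree = ntree,
                           mtry = mt, seed = derive_seed(seed, "tune", mt, i))
      ok <- !is.na(fit$oob)
      stats::cor(fit$oob[ok], st$train_table$age_start[ok])^2
    }, numeric(1)))
  }, numeric(1))
  grid[which.max(r2)]
}

#' Train one clock model
#'
#' @param train_set An imputed set (list with `train_table`,
#'   `split_index`, `imputation_index`).
#' @param features Feature column names (identical across all models).
#' @param mtry,ntree,seed Forest parameters; the forest seed is derived
#'   from `(seed, split_index, imputation_index)`.
#' @return A `clock_model`: list with the fitted forest, feature list and
#'   set indices.
#' @export
train_clock <- function(train_set, features, mtry, ntree = 2000L, seed = 1L) {
  forest <- rf_regression(set_features(train_set$train_table, features),
                          train_set$train_table$age_start,
                          ntree = ntree, mtry = mtry,
                          seed = derive_seed(seed, "forest",
                                             train_set$split_index,
                                             train_set$imputation_index))
  structure(list(forest = forest, features = features,
                 split_index = train_set$split_index,
                 imputation_index = train_set$imputation_index,
                 mtry = mtry, ntree = ntree),
            class = "clock_model")
}

#' Predict ages for every record from its test fold
#'
#' Each record is predicted by the models of the one split in which it is a
#' test record, once per imputation; the per-imputation predictions are
#' averaged into the record's final predicted age.
#'
#' @param models List of `clock_model`s, one per (split, imputation).
#' @param sets The matching list of imputed sets.
#' @return Age-prediction data.frame: `individual_id, year_index,
#'   known_age, predicted_age, delta_age` (delta = predicted - known).
#' @export
predict_panel <- function(models, sets) {
  stopifnot(length(models) == length(sets))
  acc <- NULL
  for (i in seq_along(models)) {
    mo <- models[[i]]; st <- sets[[i]]
    if (mo$split_index != st$split_index ||
        mo$imputation_index != st$imputation_index)
      stop("plan integrity error: models and sets misaligned")
    p <- predict(mo$forest, set_features(st$test_table, mo$features))
    d <- data.frame(individual_id = st$test_table$individual_id,
                    year_index = st$test_table$year_index,
                    known_age = st$test_table$age_start,
                    pred = p, stringsAsFactors = FALSE)
    acc <- if (is.null(acc)) d else rbind(acc, d)
  }
  out <- stats::aggregate(pred ~ individual_id + year_index + known_age,
                          data = acc, FUN = mean)
  names(out)[names(out) == "pred"] <- "predicted_age"
  out$delta_age <- out$predicted_age - out$known_age
  out[order(out$individual_id, out$year_index), , drop = FALSE]
}

#' Clock accuracy metrics
#'
#' R^2 is the squared Pearson correlation between predicted and known age
#' (not 1 - SSE/SST, which differs under miscalibration); the slope is from
#' an ordinary least-squares fit of predicted on known age, so values below
#' 1 indicate prediction compression.
#'
#' @param preds Age predictions from [predict_panel()].
#' @return List `r_squared`, `median_abs_error`, `slope_pred_vs_known`,
#'   `n`, `r2_definition`.
#' @export
clock_metrics <- function(preds) {
  if (nrow(preds) < 3L) stop("metrics error: need at least 3 predictions")
  if (stats::sd(preds$known_age) == 0)
    stop("metrics error: zero variance in known age")
  fit <- stats::lm(predicted_age ~ known_age, data = preds)
  list(r_squared = stats::cor(preds$predicted_age, preds$known_age)^2,
       median_abs_error = stats::median(abs(preds$predicted_age -
                                              preds$known_age)),
       slope_pred_vs_known = unname(stats::coef(fit)[2]),
       n = nrow(preds),
       r2_definition = "squared Pearson correlation")
}

#' Relative age and per-individual lifetime means
#'
#' Relative age is the residual of a pooled OLS regression of predicted on
#' known age over all individual-years; positive values mark individuals
#' predicted old-for-age after removing the clock's calibration line. The
#' residuals sum to zero and are uncorrelated with known age by
#' construction.
#'
#' @param preds Age predictions from [predict_panel()].
#' @return List with `preds` (a `relative_age` column added), `lifetime`
#'   (data.frame `individual_id, lifetime_relative_age, n_years`), and the
#'   calibration `intercept` and `slope`.
#' @export
relative_age <- function(preds) {
  if (nrow(preds) < 3L) stop("need at least 3 predictions")
  fit <- stats::lm(predicted_age ~ known_age, data = preds)
  preds$relative_age <- unname(stats::residuals(fit))
  lt <- stats::aggregate(relative_age ~ individual_id, data = preds,
                         FUN = mean)
  names(lt)[2] <- "lifetime_relative_age"
  lt$n_years <- as.integer(table(preds$individual_id)[lt$individual_id])
  list(preds = preds, lifetime = lt,
       intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]))
}

#' Repeatability of relative age
#'
#' Intraclass correlation from a random-intercept model of relative age
#' grouped by individual: between-individual variance over total variance,
#' clamped to `[0, 1]`.
#'
#' @param preds Age predictions carrying a `relative_age` column.
#' @return Repeatability (proportion).
#' @export
repeatability <- function(preds) {
  stopifnot("relative_age" %in% names(preds))
  counts <- table(preds$individual_id)
  if (length(counts) < 2L || !any(counts >= 2L))
    stop("repeatability undefined: need >= 2 individuals, >= 1 with repeats")
  fit <- suppressMessages(
    lme4::lmer(relative_age ~ 1 + (1 | individual_id), data = preds,
               REML = TRUE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  vb <- vc$vcov[vc$grp == "individual_id"]
  vw <- vc$vcov[vc$grp == "Residual"]
  max(0, min(1, vb / (vb + vw)))
}
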