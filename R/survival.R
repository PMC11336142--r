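#' Lifetime survival records
#'
#' One counting-process interval per individual, from first observed adult
#' age (delayed entry) to death or censoring, carrying the individual's
#' lifetime mean relative age as a fixed covariate.
#'
#' @param lifetime Data.frame `individual_id, lifetime_relative_age` (from
#'   [relative_age()]).
#' @param vitals Vital-status table `individual_id, entry_age, end_age,
#'   event`.
#' @param first_observed Optional data.frame `individual_id, age` overriding
#'   entry ages (delayed entry at first observation).
#' @return Survival-interval data.frame `individual_id, start_age,
#'   stop_age, event, lifetime_relative_age`.
#' @export
build_lifetime_records <- function(lifetime, vitals, first_observed = NULL) {
  ix <- match(lifetime$individual_id, vitals$individual_id)
  if (anyNA(ix))
    stop("integrity error: individuals with predictions but no vital record: ",
         paste(lifetime$individual_id[is.na(ix)][1:min(5, sum(is.na(ix)))],
               collapse = ", "))
  start <- vitals$entry_age[ix]
  if (!is.null(first_observed)) {
    fo <- first_observed$age[match(lifetime$individual_id,
                                   first_observed$individual_id)]
    start <- ifelse(is.na(fo), start, pmax(start, fo))
  }
  out <- data.frame(individual_id = lifetime$individual_id,
                    start_age = start,
                    stop_age = vitals$end_age[ix],
                    event = vitals$event[ix],
                    lifetime_relative_age = lifetime$lifetime_relative_age,
                    stringsAsFactors = FALSE)
  if (any(out$start_age >= out$stop_age))
    stop("integrity error: start_age >= stop_age")
  out
}

#' Annual (time-varying) survival records
#'
#' One interval per predicted individual-year: `(age_start, age_start + 1]`
#' or a shorter final interval ending at death/censoring, carrying that
#' year's relative age. A death whose final year was dropped by the
#' inclusion filters contributes no event (the individual's intervals end
#' at the last retained year).
#'
#' @param preds Age predictions with a `relative_age` column.
#' @param vitals Vital-status table.
#' @return Survival-interval data.frame `individual_id, start_age,
#'   stop_age, event, relative_age`.
#' @export
build_annual_records <- function(preds, vitals) {
  ix <- match(preds$individual_id, vitals$individual_id)
  if (anyNA(ix))
    stop("integrity error: predictions without vital records")
  end <- vitals$end_age[ix]
  ev <- vitals$event[ix]
  start <- preds$known_age
  stop_age <- pmin(start + 1, end)
  keep <- stop_age > start
  is_final <- abs(stop_age - end) < 1e-9
  out <- data.frame(individual_id = preds$individual_id[keep],
                    start_age = start[keep], stop_age = stop_age[keep],
                    event = as.integer(ev[keep] == 1 & is_final[keep]),
                    relative_age = preds$relative_age[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$individual_id, out$start_age), , drop = FALSE]
  by_id <- split(seq_len(nrow(out)), out$individual_id)
  for (rows in by_id) {
    if (length(rows) > 1L &&
        any(out$start_age[rows][-1] < out$stop_age[rows][-length(rows)] - 1e-9))
      stop("integrity error: overlapping intervals for an individual")
  }
  out
}

#' Fit a Cox proportional hazards model on counting-process records
#'
#' Efron tie handling; delayed entry and time-varying covariates through
#' `(start, stop]` risk sets; optional cluster-robust (grouped sandwich)
#' standard errors.
#'
#' @param records Survival-interval data.frame with `start_age, stop_age,
#'   event` and the covariate columns.
#' @param covariate_names Covariates to include.
#' @param cluster Optional name of a grouping column (e.g.
#'   `"individual_id"`) for robust SEs.
#' @param ties Tie-handling approximation (`"efron"` default, or
#'   `"breslow"`).
#' @return List of class `cox_result`: per-covariate data.frame `results`
#'   (`coefficient, hazard_ratio, se, ci_low, ci_high, p_value`), `se_type`,
#'   `n_events`, and the underlying `fit`.
#' @export
fit_cox <- function(records, covariate_names, cluster = NULL,
                    ties = "efron") {
  if (sum(records$event) < 1L) stop("fit error: no events")
  for (cn in covariate_names)
    if (stats::sd(records[[cn]]) == 0)
      stop("non-identifiable error: constant covariate '", cn, "'")
  f <- stats::as.formula(paste(
    "survival::Surv(start_age, stop_age, event) ~",
    paste(covariate_names, collapse = " + ")))
  fit <- if (is.null(cluster))
    survival::coxph(f, data = records, ties = ties)
  else
    survival::coxph(f, data = records, ties = ties,
                    cluster = records[[cluster]])
  sm <- summary(fit)
  co <- sm$coefficients
  se_col <- if ("robust se" %in% colnames(co)) "robust se" else "se(coef)"
  se <- co[, se_col]
  beta <- co[, "coef"]
  res <- data.frame(covariate = rownames(co), coefficient = unname(beta),
                    hazard_ratio = unname(exp(beta)), se = unname(se),
                    ci_low = unname(exp(beta - 1.96 * se)),
                    ci_high = unname(exp(beta + 1.96 * se)),
                    p_value = unname(2 * stats::pnorm(-abs(beta / se))),
                    stringsAsFactors = FALSE)
  structure(list(results = res,
                 se_type = if (is.null(cluster)) "model" else "cluster-robust",
                 n_events = sum(records$event), fit = fit),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat("<cox_result> ", x$n_events, " events, ", x$se_type, " SEs\n", sep = "")
  print(format(x$results, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Score cumulative early-life adversity
#'
#' Binary sources (maternal death, close-in-age sibling, drought) are used
#' directly; continuous sources are binarized at the most-adverse quartile
#' of the supplied population: maternal social connectedness and maternal
#' rank flagged when at or below their 25th percentile, group size when at
#' or above its 75th percentile (thresholds inclusive on the adverse side).
#' The cumulative index is the number of flagged sources (0-6). Individuals
#' missing any source are excluded and logged.
#'
#' @param profiles Data.frame `individual_id, maternal_death,
#'   close_sibling, drought, maternal_sci, maternal_rank, group_size`.
#' @param population Optional data.frame supplying the quartile reference
#'   distributions (default: `profiles` itself).
#' @return List with `profiles` (complete rows, six `flag_*` columns and
#'   `cumulative_index` added) and `excluded` (ids with missing sources).
#' @export
cumulative_adversity <- function(profiles, population = profiles) {
  src <- c("maternal_death", "close_sibling", "drought",
           "maternal_sci", "maternal_rank", "group_size")
  stopifnot(all(c("individual_id", src) %in% names(profiles)))
  complete <- stats::complete.cases(profiles[, src])
  excluded <- profiles$individual_id[!complete]
  pr <- profiles[complete, , drop = FALSE]
  q_sci <- stats::quantile(population$maternal_sci, 0.25, na.rm = TRUE)
  q_rank <- stats::quantile(population$maternal_rank, 0.25, na.rm = TRUE)
  q_gs <- stats::quantile(population$group_size, 0.75, na.rm = TRUE)
  pr$flag_maternal_death <- pr$maternal_death == 1
  pr$flag_close_sibling <- pr$close_sibling == 1
  pr$flag_drought <- pr$drought == 1
  pr$flag_maternal_sci <- pr$maternal_sci <= q_sci
  pr$flag_maternal_rank <- pr$maternal_rank <= q_rank
  pr$flag_group_size <- pr$group_size >= q_gs
  pr$cumulative_index <- rowSums(pr[, paste0("flag_", src)])
  list(profiles = pr, excluded = excluded)
}

#' Mixed model of delta age on early-life adversity
#'
#' Linear mixed model with individual random intercepts; response is delta
#' age (predicted minus known age) per individual-year. Chronological age
#' is always a fixed effect (delta age is correlated with it by
#' construction), alongside current-condition covariates. Adversity enters
#' either as the cumulative 0-6 index (`mode = "cumulative"`) or as the six
#' separate sources (`mode = "multivariable"`, continuous sources
#' unbinned). Falls back to OLS with a flag when the random effect is
#' singular and unestimable.
#'
#' @param preds Age predictions (with `delta_age`).
#' @param profiles Scored adversity profiles from [cumulative_adversity()].
#' @param conditions Data.frame `individual_id, year_index, rank_prop,
#'   group_size, rain_anomaly` of current conditions.
#' @param mode `"cumulative"` or `"multivariable"`.
#' @return List of class `delta_age_model`: `coefficients` data.frame
#'   (`term, estimate, se, p_value`), `random_intercept_variance`, `n`,
#'   `n_individuals`, `singular_fallback`.
#' @export
fit_delta_age_lmm <- function(preds, profiles, conditions,
                              mode = c("cumulative", "multivariable")) {
  mode <- match.arg(mode)
  d <- merge(preds, conditions, by = c("individual_id", "year_index"))
  d <- merge(d, profiles, by = "individual_id")
  adv_terms <- if (mode == "cumulative") "cumulative_index" else
    c("maternal_death", "close_sibling", "drought",
      "maternal_sci", "maternal_rank", "group_size.y")
  if (mode == "multivariable" && !"group_size.y" %in% names(d))
    adv_terms[6] <- "group_size"
  cond_terms <- c("known_age", "rank_prop",
                  if ("group_size.x" %in% names(d)) "group_size.x"
                  else "group_size", "rain_anomaly")
  f <- stats::as.formula(paste("delta_age ~",
                               paste(c(adv_terms, cond_terms),
                                     collapse = " + "),
                               "+ (1 | individual_id)"))
  mixed <- tryCatch({
    fit <- suppressMessages(lme4::lmer(f, data = d, REML = TRUE))
    co <- summary(fit)$coefficients
    vc <- as.data.frame(lme4::VarCorr(fit))
    list(fit = fit, co = co,
         var_b = vc$vcov[vc$grp == "individual_id"], fallback = FALSE)
  }, error = function(e) NULL)
  if (is.null(mixed)) {
    # singular / unestimable random effect: plain OLS with a grouped
    # (by-individual) sandwich for the standard errors
    flm <- stats::lm(stats::as.formula(paste(
      "delta_age ~", paste(c(adv_terms, cond_terms), collapse = " + "))),
      data = d)
    X <- stats::model.matrix(flm)
    e <- stats::residuals(flm)
    bread <- solve(crossprod(X))
    sc <- rowsum(X * e, d$individual_id)
    V <- bread %*% crossprod(as.matrix(sc)) %*% bread
    co <- cbind(Estimate = stats::coef(flm),
                `Std. Error` = sqrt(diag(V)),
                `t value` = stats::coef(flm) / sqrt(diag(V)))
    mixed <- list(fit = flm, co = co, var_b = 0, fallback = TRUE)
  }
  co <- mixed$co
  coefs <- data.frame(term = rownames(co), estimate = co[, "Estimate"],
                      se = co[, "Std. Error"],
                      p_value = 2 * stats::pnorm(-abs(co[, "t value"])),
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = coefs,
                 random_intercept_variance = mixed$var_b,
                 n = nrow(d), n_individuals = length(unique(d$individual_id)),
                 singular_fallback = mixed$fallback, fit = mixed$fit),
            class = "delta_age_model")
}

#' Cox model of relative age controlling for adversity
#'
#' Joint Cox fit of relative age and the cumulative adversity index, with
#' an attenuation diagnostic: the ratio of the relative-age log-hazard
#' coefficient with vs without the adversity covariate.
#'
#' @param records Lifetime survival intervals carrying
#'   `lifetime_relative_age`.
#' @param profiles Scored adversity profiles (merged by `individual_id`;
#'   individuals without adversity data are dropped).
#' @param cluster Optional clustering column passed to [fit_cox()].
#' @return List: `joint` (cox_result for both covariates), `without`
#'   (relative age alone on the same subset), `attenuation` (coefficient
#'   ratio with/without), `n`.
#' @export
fit_cox_with_adversity <- function(records, profiles, cluster = NULL) {
  d <- merge(records, profiles[, c("individual_id", "cumulative_index")],
             by = "individual_id")
  rel_cov <- intersect(c("lifetime_relative_age", "relative_age"), names(d))[1]
  without <- fit_cox(d, rel_cov, cluster = cluster)
  joint <- fit_cox(d, c(rel_cov, "cumulative_index"), cluster = cluster)
  b_with <- joint$results$coefficient[joint$results$covariate == rel_cov]
  b_wo <- without$results$coefficient[without$results$covariate == rel_cov]
  list(joint = joint, without = without,
       attenuation = b_with / b_wo, n = nrow(d))
}
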