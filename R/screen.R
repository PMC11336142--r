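#' AIC tie-break rule
#'
#' Given candidate model fits summarized by AIC and degrees of freedom,
#' returns the index of the chosen model: the AIC minimizer, except that
#' among all models within 2 AIC units of the minimum the one with the
#' fewest degrees of freedom wins (first in input order on exact ties).
#'
#' @param aic Numeric vector of AIC values (NA = unfittable).
#' @param df Integer vector of model degrees of freedom.
#' @return Index of the selected model.
#' @export
select_by_aic <- function(aic, df) {
  stopifnot(length(aic) == length(df))
  ok <- which(is.finite(aic))
  if (!length(ok)) stop("screening error: no fittable model")
  near <- ok[aic[ok] <= min(aic[ok]) + 2]
  near[which.min(df[near])]
}

trait_kind <- function(panel, trait) registry_kinds(panel$registry)[[trait]]

screen_formula <- function(trait, fixed, random = "(1 | individual_id)",
                           age_terms = FALSE) {
  rhs <- c(fixed, if (age_terms) c("age_c", "age_c2"), random)
  if (!length(rhs)) rhs <- "1"
  stats::as.formula(paste(trait, "~", paste(rhs, collapse = " + ")))
}

prepare_screen_data <- function(panel, trait) {
  d <- panel$records
  d <- d[!is.na(d[[trait]]), , drop = FALSE]
  d$age_c <- d$age_start - mean(d$age_start)
  d$age_c2 <- d$age_c^2
  d
}

fit_screen_model <- function(trait, kind, fixed, data, age_terms = FALSE) {
  if (kind == "categorical3") {
    rhs <- c("1", fixed, if (age_terms) c("age_c", "age_c2"))
    X <- stats::model.matrix(
      stats::as.formula(paste("~", paste(rhs, collapse = " + "))), data)
    return(multinom_fit(data[[trait]], X))
  }
  f <- screen_formula(trait, fixed, age_terms = age_terms)
  suppressMessages(suppressWarnings(
    if (kind == "continuous")
      lme4::lmer(f, data = data, REML = FALSE)
    else
      lme4::glmer(f, data = data, family = stats::binomial, nAGQ = 0L)
  ))
}

model_aic_df <- function(fit) {
  if (is.list(fit) && is.numeric(fit$logLik))  # multinom_fit result
    return(c(aic = -2 * fit$logLik + 2 * fit$df, df = fit$df))
  ll <- stats::logLik(fit)
  c(aic = -2 * as.numeric(ll) + 2 * attr(ll, "df"), df = attr(ll, "df"))
}

#' Select the base covariate model for one trait
#'
#' Exhaustively fits all fixed-effect subsets of the candidate covariates
#' (random-effect structure held fixed at an individual intercept;
#' multinomial traits carry no random effect), compares them by maximum
#' likelihood AIC, and applies the within-2-AIC lowest-df tie-break.
#'
#' @param trait Trait name.
#' @param panel A `cohort_panel` containing the trait and candidates.
#' @param candidates Character vector of candidate covariates (<= 10).
#' @return List of class `candidate_model_spec` with `trait`,
#'   `fixed_effects`, `family`, `aic`, `df`.
#' @export
select_base_model <- function(trait, panel,
                              candidates = panel$registry[[trait]]$candidate_covariates) {
  if (length(candidates) > 10L)
    stop("screening error: more than 10 candidate covariates")
  kind <- trait_kind(panel, trait)
  data <- prepare_screen_data(panel, trait)
  subsets <- if (length(candidates)) {
    grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(candidates)))
    lapply(seq_len(nrow(grid)), function(i) candidates[unlist(grid[i, ])])
  } else list(character())
  fits <- lapply(subsets, function(fx) {
    tryCatch(fit_screen_model(trait, kind, fx, data),
             error = function(e) NULL)
  })
  stats <- t(vapply(fits, function(f) {
    if (is.null(f)) c(aic = NA_real_, df = NA_real_) else model_aic_df(f)
  }, numeric(2)))
  pick <- select_by_aic(stats[, "aic"], stats[, "df"])
  structure(
    list(trait = trait, fixed_effects = subsets[[pick]],
         family = switch(kind, continuous = "gaussian-lmm",
                         binary = "binomial-glmm",
                         categorical3 = "multinomial"),
         aic = unname(stats[pick, "aic"]), df = unname(stats[pick, "df"])),
    class = "candidate_model_spec")
}

unfit_result <- function(trait, reason, aic = NA_real_, df = NA_real_) {
  data.frame(trait = trait, linear_coef = NA_real_, quadratic_coef = NA_real_,
             p_linear = NA_real_, p_quadratic = NA_real_,
             aic_base = aic, df_base = df, significant = FALSE,
             unfit = TRUE, reason = reason, stringsAsFactors = FALSE)
}

#' Test linear and quadratic age terms for one trait
#'
#' Refits the base model with centered age and centered-age-squared added
#' and reports both coefficients with per-term p-values: Wald normal
#' approximation for mixed models, likelihood-ratio tests (joint over the
#' two outcome contrasts) for multinomial traits. The trait is significant
#' when either term has p <= alpha.
#'
#' @param trait Trait name.
#' @param base A `candidate_model_spec` from [select_base_model()].
#' @param panel A `cohort_panel`.
#' @param alpha Significance level (default 0.05).
#' @return One-row data.frame (an age-screen result): `trait, linear_coef,
#'   quadratic_coef, p_linear, p_quadratic, aic_base, df_base, significant,
#'   unfit, reason`. Multinomial coefficients are the level-3 vs level-1
#'   contrast.
#' @export
test_age_terms <- function(trait, base, panel, alpha = 0.05) {
  kind <- trait_kind(panel, trait)
  data <- prepare_screen_data(panel, trait)
  if (nrow(data) < 10L || length(unique(data[[trait]])) < 2L)
    return(unfit_result(trait, "zero variance or too few observations"))
  res <- tryCatch({
    if (kind == "categorical3") {
      rhs0 <- c("1", base$fixed_effects)
      Xf <- stats::model.matrix(stats::as.formula(
        paste("~", paste(c(rhs0, "age_c", "age_c2"), collapse = " + "))), data)
      full <- multinom_fit(data[[trait]], Xf)
      drop1 <- multinom_fit(data[[trait]],
                            Xf[, colnames(Xf) != "age_c", drop = FALSE])
      drop2 <- multinom_fit(data[[trait]],
                            Xf[, colnames(Xf) != "age_c2", drop = FALSE])
      lrt <- function(red) {
        stat <- 2 * (full$logLik - red$logLik)
        stats::pchisq(max(stat, 0), df = full$df - red$df, lower.tail = FALSE)
      }
      co <- full$coef  # rows = contrasts (levels 2, 3 vs 1)
      data.frame(trait = trait,
                 linear_coef = co[nrow(co), "age_c"],
                 quadratic_coef = co[nrow(co), "age_c2"],
                 p_linear = lrt(drop1), p_quadratic = lrt(drop2),
                 aic_base = base$aic, df_base = base$df,
                 significant = NA, unfit = FALSE, reason = "",
                 stringsAsFactors = FALSE)
    } else {
      fit <- fit_screen_model(trait, kind, base$fixed_effects, data,
                              age_terms = TRUE)
      co <- summary(fit)$coefficients
      z <- co[, "Estimate"] / co[, "Std. Error"]
      p <- 2 * stats::pnorm(-abs(z))
      data.frame(trait = trait,
                 linear_coef = co["age_c", "Estimate"],
                 quadratic_coef = co["age_c2", "Estimate"],
                 p_linear = unname(p["age_c"]),
                 p_quadratic = unname(p["age_c2"]),
                 aic_base = base$aic, df_base = base$df,
                 significant = NA, unfit = FALSE, reason = "",
                 stringsAsFactors = FALSE)
    }
  }, error = function(e) unfit_result(trait, conditionMessage(e),
                                      base$aic, base$df))
  if (!res$unfit)
    res$significant <- isTRUE(res$p_linear <= alpha) ||
      isTRUE(res$p_quadratic <= alpha)
  res
}

#' Screen all registry traits for age associations
#'
#' Runs the two-stage screen (AIC base-model selection, then age-term
#' testing) over every trait in the registry and returns the clock feature
#' set: traits whose linear or quadratic age term is significant at alpha.
#' Unfit traits are flagged and excluded, never aborting the screen.
#'
#' @param panel A `cohort_panel` (continuous traits should be standardized
#'   first so linear coefficients read as SD per year).
#' @param registry Optional registry subset to screen (default: the panel's).
#' @param alpha Per-term significance level.
#' @return List with `results` (one row per trait) and `features`
#'   (significant trait names, registry order).
#' @export
screen_traits <- function(panel, registry = panel$registry, alpha = 0.05) {
  rows <- lapply(registry_names(registry), function(tr) {
    base <- tryCatch(select_base_model(tr, panel),
                     error = function(e) NULL)
    if (is.null(base)) return(unfit_result(tr, "no fittable base model"))
    test_age_terms(tr, base, panel, alpha = alpha)
  })
  results <- do.call(rbind, rows)
  list(results = results,
       features = results$trait[results$significant & !results$unfit])
}

# ---- multinomial logistic regression (softmax, reference level 1) -----

#' Multinomial logistic fit by maximum likelihood
#'
#' Small softmax-regression fitter used for 3-level categorical traits:
#' levels `1..K` with level 1 as reference, BFGS on the negative
#' log-likelihood with analytic gradient.
#'
#' @param y Integer responses in `1..K`.
#' @param X Model matrix (including intercept).
#' @return List with `coef` ((K-1) x p matrix, rows = contrasts vs level 1),
#'   `logLik`, `df`.
#' @keywords internal
multinom_fit <- function(y, X) {
  y <- as.integer(y)
  K <- max(y)
  lev <- sort(unique(y))
  if (length(lev) < 2L) stop("multinomial response has a single level")
  p <- ncol(X)
  Y <- matrix(0, nrow(X), K)
  Y[cbind(seq_along(y), y)] <- 1
  nll <- function(par) {
    B <- matrix(par, nrow = K - 1L)
    eta <- cbind(0, X %*% t(B))
    eta <- eta - apply(eta, 1, max)
    -sum(eta[cbind(seq_along(y), y)] - log(rowSums(exp(eta))))
  }
  grad <- function(par) {
    B <- matrix(par, nrow = K - 1L)
    eta <- cbind(0, X %*% t(B))
    eta <- eta - apply(eta, 1, max)
    P <- exp(eta) / rowSums(exp(eta))
    G <- t(P[, -1L, drop = FALSE] - Y[, -1L, drop = FALSE]) %*% X
    as.numeric(G)
  }
  opt <- stats::optim(rep(0, (K - 1L) * p), nll, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  coef <- matrix(opt$par, nrow = K - 1L, dimnames = list(NULL, colnames(X)))
  list(coef = coef, logLik = -opt$value, df = (K - 1L) * p)
}
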