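#' Derive a reproducible sub-stream seed
#'
#' All stage seeds are derived from one master seed plus a stage label (and
#' optional integer indices) so that stages are independently reproducible.
#' The result is a positive integer below 2^31.
#'
#' @param master Master integer seed.
#' @param label Stage label string.
#' @param ... Optional integer indices (split, imputation, replicate, ...).
#' @export
derive_seed <- function(master, label, ...) {
  idx <- c(...)
  h <- as.double(master) %% 2147483647
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 2147483647
  for (k in idx) h <- (h * 131 + as.double(k) + 17) %% 2147483647
  as.integer(h %% 2147483562 + 1)
}

SHAPE_CLASSES <- c("convex", "linear_decreasing", "linear_increasing",
                   "plateauing", "ascending", "concave")

#' Simulation configuration
#'
#' Describes the generative world for a synthetic cohort: age-shaped trait
#' trajectories in six shape classes, individual random intercepts, a latent
#' per-individual frailty offset (in years of biological age) that shifts
#' both trait trajectories and the mortality hazard, six sources of
#' early-life adversity feeding frailty, missingness, and right-censoring.
#'
#' Default scale mirrors a long-term primate field study: 319 adult females
#' entering at age 4, followed to at most age 27, 49 traits (38 continuous,
#' 7 binary, 4 three-level categorical), 26% missing cells, baseline annual
#' mortality hazard 0.093.
#'
#' @param n_individuals Number of individuals.
#' @param entry_age Adult entry age in years.
#' @param max_age Administrative censoring age in years.
#' @param registry Optional [trait_registry()]; default [default_registry()]
#'   scaled by the three kind counts.
#' @param n_continuous,n_binary,n_categorical3 Trait counts (ignored when
#'   `registry` is supplied).
#' @param shape_mix Named proportions over the six shape classes
#'   `r paste(SHAPE_CLASSES, collapse=", ")`; must sum to 1.
#' @param effect_linear Linear age effect magnitude, SD per year.
#' @param effect_quad Quadratic age effect magnitude, SD per year^2.
#' @param individual_sd SD of individual random intercepts (trait SD units).
#' @param residual_sd Residual SD (trait SD units).
#' @param frailty_sd SD of the latent frailty offset, years.
#' @param frailty_trait_loading Years of apparent trait aging per frailty
#'   year (lambda; frailty enters traits as an age offset `a + lambda f_i`).
#' @param missing_rate Target proportion of missing trait cells.
#' @param missing_mechanism `"MCAR"` or `"MAR"` (probability decreasing with
#'   observation days).
#' @param baseline_hazard Baseline annual mortality hazard past entry age.
#' @param frailty_log_hazard Log-hazard increase per frailty year.
#' @param censoring_hazard Independent annual dropout (censoring) hazard.
#' @param adversity_prevalences Six prevalences for the adversity sources
#'   (binary sources use them directly; continuous sources are binarized at
#'   the most-adverse quartile downstream, so their entries are nominal).
#' @param adversity_frailty_effect Years of frailty added per experienced
#'   adversity source.
#' @param adversity_coverage Proportion of individuals with adversity data
#'   (the rest have missing early-life records).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 319L, entry_age = 4, max_age = 27,
                       registry = NULL,
                       n_continuous = 38L, n_binary = 7L, n_categorical3 = 4L,
                       shape_mix = NULL,
                       effect_linear = 0.1, effect_quad = 0.01,
                       individual_sd = 0.3, residual_sd = 0.5,
                       frailty_sd = 1, frailty_trait_loading = 1,
                       missing_rate = 0.26, missing_mechanism = "MCAR",
                       baseline_hazard = 0.093, frailty_log_hazard = 0.3,
                       censoring_hazard = 0.05,
                       adversity_prevalences = rep(0.25, 6),
                       adversity_frailty_effect = 0.15,
                       adversity_coverage = 0.8) {
  if (is.null(registry))
    registry <- default_registry(n_continuous, n_binary, n_categorical3)
  if (is.null(shape_mix)) {
    shape_mix <- rep(1 / 6, 6)
    names(shape_mix) <- SHAPE_CLASSES
  }
  if (!all(names(shape_mix) %in% SHAPE_CLASSES))
    stop("config error: unknown shape class in shape_mix")
  if (abs(sum(shape_mix) - 1) > 1e-8)
    stop("config error: shape_mix must sum to 1")
  sds <- c(individual_sd, residual_sd, frailty_sd)
  if (any(sds < 0)) stop("config error: SDs must be >= 0")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("config error: missing_rate must be in [0, 1)")
  if (baseline_hazard <= 0) stop("config error: baseline_hazard must be > 0")
  if (length(adversity_prevalences) != 6L ||
      any(adversity_prevalences < 0 | adversity_prevalences > 1))
    stop("config error: adversity_prevalences must be six proportions")
  structure(as.list(environment()), class = "sim_config")
}

# per-trait generating coefficients realizing the six shape classes on the
# raw-age scale; vertex placement makes the curvature visible inside the
# observed age range
shape_coefs <- function(shape, b1, b2, entry_age, max_age) {
  mid <- (entry_age + max_age) / 2
  switch(shape,
    linear_increasing = c(b1, 0),
    linear_decreasing = c(-b1, 0),
    convex            = c(2 * b2 * mid, -b2),        # rises, peaks mid-life
    concave           = c(-2 * b2 * mid, b2),        # falls, troughs mid-life
    plateauing        = c(2 * b2 * max_age, -b2),    # rising, flattening
    ascending         = c(-2 * b2 * entry_age, b2),  # accelerating rise
    stop("unknown shape class: ", shape))
}

sim_trait_coefs <- function(config) {
  traits <- registry_names(config$registry)
  n <- length(traits)
  counts <- round(config$shape_mix * n)
  while (sum(counts) < n) counts[which.max(config$shape_mix)] <-
      counts[which.max(config$shape_mix)] + 1L
  while (sum(counts) > n) counts[which.max(counts)] <-
      counts[which.max(counts)] - 1L
  shapes <- rep(names(config$shape_mix), counts)[seq_len(n)]
  co <- t(vapply(shapes, shape_coefs, numeric(2),
                 b1 = config$effect_linear, b2 = config$effect_quad,
                 entry_age = config$entry_age, max_age = config$max_age))
  data.frame(trait = traits, kind = unname(registry_kinds(config$registry)),
             shape = shapes, beta1 = co[, 1], beta2 = co[, 2],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Simulate survival times from a frailty-dependent hazard
#'
#' Death age past `entry_age` is drawn from a constant individual hazard
#' `baseline_hazard * exp(frailty_log_hazard * f_i)`; an independent
#' exponential dropout process and administrative censoring at `max_age`
#' right-censor the record.
#'
#' @param truth A `sim_truth` (or any list with a numeric `frailty` vector
#'   and `individual_id`).
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return Vital-status data.frame: `individual_id, entry_age, end_age,
#'   event` (1 = death, 0 = censored).
#' @export
simulate_survival <- function(truth, config, seed) {
  set.seed(seed)
  f <- truth$frailty
  n <- length(f)
  haz <- config$baseline_hazard * exp(config$frailty_log_hazard * f)
  t_death <- config$entry_age + stats::rexp(n, rate = haz)
  t_cens <- if (config$censoring_hazard > 0)
    config$entry_age + stats::rexp(n, rate = config$censoring_hazard)
  else rep(Inf, n)
  end <- pmin(t_death, t_cens, config$max_age)
  event <- as.integer(t_death <= pmin(t_cens, config$max_age))
  data.frame(individual_id = truth$individual_id,
             entry_age = config$entry_age, end_age = end, event = event,
             stringsAsFactors = FALSE)
}

#' Simulate a synthetic cohort with known ground truth
#'
#' Generates individuals with latent frailty (partly driven by early-life
#' adversity), frailty-dependent survival, and annual trait trajectories in
#' six age-shape classes. Continuous traits follow
#' `b0_i + beta1 * (a + lambda f_i) + beta2 * (a + lambda f_i)^2 + eps`;
#' binary and 3-level categorical traits use the analogous linear predictor
#' through logistic and ordinal-logistic links. Death or dropout truncates
#' the final year's record (reducing its observation days), deliberately
#' producing some death-years that fail the 60-day inclusion filter.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return List with `panel` (a [cohort_panel()] with covariate columns
#'   `rank_prop, group_size, rain_anomaly, alive_at_year_end`), `truth`
#'   (class `sim_truth`: frailty, adversity sources and flags, generating
#'   coefficients, realized end ages), `vitals`, and `adversity` (the
#'   early-life table with `NA` rows for uncovered individuals).
#' @export
simulate_cohort <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  ids <- sprintf("F%04d", seq_len(config$n_individuals))
  n <- config$n_individuals

  # --- adversity sources and frailty ---------------------------------
  set.seed(derive_seed(seed, "adversity"))
  prev <- config$adversity_prevalences
  adv <- data.frame(
    individual_id = ids,
    maternal_death = stats::rbinom(n, 1, prev[1]),
    close_sibling = stats::rbinom(n, 1, prev[2]),
    drought = stats::rbinom(n, 1, prev[3]),
    maternal_sci = stats::rnorm(n),   # social connectedness; low = adverse
    maternal_rank = stats::runif(n),  # proportional rank; low = adverse
    group_size = round(stats::runif(n, 10, 45)),  # large = adverse
    stringsAsFactors = FALSE)
  flags <- cbind(
    maternal_death = adv$maternal_death == 1,
    close_sibling = adv$close_sibling == 1,
    drought = adv$drought == 1,
    maternal_sci = adv$maternal_sci <= stats::quantile(adv$maternal_sci, 0.25),
    maternal_rank = adv$maternal_rank <= stats::quantile(adv$maternal_rank, 0.25),
    group_size = adv$group_size >= stats::quantile(adv$group_size, 0.75))
  adv_index <- rowSums(flags)
  covered <- stats::runif(n) < config$adversity_coverage

  set.seed(derive_seed(seed, "frailty"))
  frailty <- stats::rnorm(n, 0, config$frailty_sd) +
    config$adversity_frailty_effect * adv_index

  truth <- structure(
    list(individual_id = ids, frailty = frailty,
         adversity_flags = flags, adversity_index = adv_index,
         adversity_covered = covered,
         coefs = sim_trait_coefs(config)),
    class = "sim_truth")

  # --- survival ------------------------------------------------------
  vitals <- simulate_survival(truth, config, derive_seed(seed, "survival"))
  truth$end_age <- vitals$end_age
  truth$event <- vitals$event

  # --- annual records ------------------------------------------------
  set.seed(derive_seed(seed, "panel"))
  rows <- lapply(seq_len(n), function(i) {
    starts <- seq(config$entry_age, by = 1,
                  length.out = max(1, ceiling(truth$end_age[i] -
                                                config$entry_age)))
    starts <- starts[starts < truth$end_age[i]]
    if (!length(starts)) return(NULL)
    frac <- pmin(1, truth$end_age[i] - starts)
    data.frame(individual_id = ids[i],
               year_index = as.integer(starts - config$entry_age),
               age_start = starts, year_frac = frac,
               stringsAsFactors = FALSE)
  })
  rec <- do.call(rbind, rows)
  m <- nrow(rec)
  base_days <- round(365 * stats::runif(m, 0.55, 0.95))
  low_effort <- stats::runif(m) < 0.02
  base_days[low_effort] <- round(stats::runif(sum(low_effort), 20, 120))
  rec$observation_days <- as.integer(pmax(1, round(base_days * rec$year_frac)))
  rec$alive_at_year_end <- as.integer(rec$year_frac >= 1)

  # current-condition covariates (per individual-year)
  idx <- match(rec$individual_id, ids)
  rank_base <- stats::runif(n)
  gs_base <- round(stats::runif(n, 8, 40))
  rec$rank_prop <- pmin(1, pmax(0, rank_base[idx] + stats::rnorm(m, 0, 0.08)))
  rec$group_size <- pmax(4, round(gs_base[idx] + stats::rnorm(m, 0, 2)))
  rec$rain_anomaly <- stats::rnorm(m)

  # --- trait values --------------------------------------------------
  set.seed(derive_seed(seed, "traits"))
  co <- truth$coefs
  a_eff <- rec$age_start + config$frailty_trait_loading * frailty[idx]
  mid <- (config$entry_age + config$max_age) / 2
  b0 <- matrix(stats::rnorm(n * nrow(co), 0, config$individual_sd),
               nrow = n)  # individual random intercepts per trait
  for (j in seq_len(nrow(co))) {
    lp <- co$beta1[j] * a_eff + co$beta2[j] * a_eff^2
    if (co$kind[j] == "continuous") {
      rec[[co$trait[j]]] <- b0[idx, j] + lp +
        stats::rnorm(m, 0, config$residual_sd)
    } else {
      # center the linear predictor at mid-life so levels stay balanced
      lp0 <- co$beta1[j] * mid + co$beta2[j] * mid^2
      eta <- 2 * (lp - lp0) + b0[idx, j]
      if (co$kind[j] == "binary") {
        rec[[co$trait[j]]] <- stats::rbinom(m, 1, stats::plogis(eta))
      } else {
        latent <- eta + stats::rlogis(m)
        rec[[co$trait[j]]] <- as.numeric(cut(latent, c(-Inf, -0.8, 0.8, Inf),
                                             labels = FALSE))
      }
    }
  }
  rec$year_frac <- NULL

  panel <- cohort_panel(rec, config$registry,
                        covariates = c("alive_at_year_end", "rank_prop",
                                       "group_size", "rain_anomaly"),
                        provenance = sprintf("simulate_cohort(seed=%d)", seed))

  adv_out <- adv
  adv_out[!covered, setdiff(names(adv_out), "individual_id")] <- NA
  list(panel = panel, truth = truth, vitals = vitals, adversity = adv_out)
}

#' Impose missingness on trait cells
#'
#' @param panel A `cohort_panel`.
#' @param rate Target proportion of missing trait cells, in `[0, 1)`.
#' @param mechanism `"MCAR"` (uniform) or `"MAR"` (cell missingness
#'   probability decreases with the record's observation days; mean
#'   probability equals `rate`).
#' @param seed Integer seed.
#' @return The panel with trait cells set to `NA`; observed cells unchanged.
#' @export
impose_missingness <- function(panel, rate, mechanism = c("MCAR", "MAR"),
                               seed = 1L) {
  mechanism <- match.arg(mechanism)
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  if (rate == 0) return(panel)
  set.seed(seed)
  rec <- panel$records
  traits <- panel_traits(panel)
  m <- nrow(rec)
  p_row <- if (mechanism == "MCAR") rep(rate, m) else {
    od <- rec$observation_days
    w <- stats::plogis(-scale(od)[, 1])      # fewer days -> more missing
    pmin(0.95, rate * w / mean(w))
  }
  for (tr in traits) {
    drop <- stats::runif(m) < p_row
    rec[[tr]][drop] <- NA
  }
  cohort_panel(rec, panel$registry, covariates = panel$covariates,
               provenance = panel$provenance, validate = FALSE)
}
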