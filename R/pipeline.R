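#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run. Either `sim` (a
#' [sim_config()]) or the three input paths (`panel_path`, `vitals_path`,
#' `adversity_path`, with `registry`) must be supplied.
#'
#' @param sim Optional [sim_config()] for a synthetic run.
#' @param panel_path,vitals_path,adversity_path CSV inputs for a data run.
#' @param registry Trait registry for data runs (defaults to `sim$registry`).
#' @param seed Master seed (mandatory); all stage seeds derive from it.
#' @param min_days,max_missing Inclusion-filter thresholds.
#' @param run_screen Run the age screen and restrict the clock to
#'   significant traits (`FALSE` uses all registry traits).
#' @param n_splits,m,k_donors,n_burn Split / imputation parameters.
#' @param ntree Trees per forest.
#' @param mtry_grid Candidate mtry values (default: p/6, p/3, 2p/3).
#' @param tune_ntree Trees used during mtry tuning.
#' @param standardize_scope `"train"` (training-partition statistics applied
#'   to the test partition; leakage-safe default) or `"global"`.
#' @param restricted Also fit the restricted clock (mortality-linked traits
#'   excluded).
#' @param out_dir Optional artifact directory.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, panel_path = NULL, vitals_path = NULL,
                            adversity_path = NULL, registry = NULL,
                            seed, min_days = 60L, max_missing = NULL,
                            run_screen = TRUE,
                            n_splits = 5L, m = 5L, k_donors = 5L, n_burn = 3L,
                            ntree = 500L, mtry_grid = NULL, tune_ntree = 200L,
                            standardize_scope = "train", restricted = TRUE,
                            out_dir = NULL) {
  if (missing(seed)) stop("config error: seed is mandatory")
  if (is.null(sim) && is.null(panel_path))
    stop("config error: supply either sim or panel_path")
  if (is.null(registry) && !is.null(sim)) registry <- sim$registry
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full clock pipeline
#'
#' filter -> screen -> neighbor fill -> splits -> split-wise PMM imputation
#' -> standardization -> mtry tuning -> forest training -> prediction
#' averaging -> relative age / repeatability -> lifetime and time-varying
#' Cox models -> adversity models, with an optional restricted-clock rerun.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return List of stage artifacts (see elements `preds`, `metrics`,
#'   `repeatability`, `cox_lifetime`, `cox_annual`, `adversity`,
#'   `restricted`, `manifest`, ...). If `config$out_dir` is set, artifact
#'   CSV/JSON files and a run manifest are written there.
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  say <- function(...) if (!quiet) message(...)

  # --- inputs --------------------------------------------------------
  if (!is.null(config$sim)) {
    say("simulating cohort")
    simd <- simulate_cohort(config$sim, derive_seed(seed, "simulate"))
    panel <- simd$panel
    if (config$sim$missing_rate > 0)
      panel <- impose_missingness(panel, config$sim$missing_rate,
                                  config$sim$missing_mechanism,
                                  derive_seed(seed, "missing"))
    vitals <- simd$vitals
    adversity <- simd$adversity
    truth <- simd$truth
  } else {
    panel <- read_panel(config$panel_path, config$registry)
    vitals <- utils::read.csv(config$vitals_path, stringsAsFactors = FALSE)
    adversity <- if (!is.null(config$adversity_path))
      utils::read.csv(config$adversity_path, stringsAsFactors = FALSE)
    truth <- NULL
  }

  # --- inclusion filters ---------------------------------------------
  flt <- apply_inclusion_filters(panel, min_days = config$min_days,
                                 max_missing = config$max_missing)
  panel <- flt$panel
  say(sprintf("retained %d records (%d dropped)", nrow(panel$records),
              nrow(flt$report)))

  # --- age screen ----------------------------------------------------
  screen <- NULL
  features <- panel_traits(panel)
  if (config$run_screen) {
    say("screening traits for age associations")
    spanel <- standardize_traits(panel)$panel  # SD-per-year coefficients
    screen <- screen_traits(spanel)
    features <- screen$features
    if (length(features) < 2L)
      stop("stage error [screen]: fewer than 2 age-associated traits")
  }
  clock_registry <- registry_subset(panel$registry, features)
  cpanel <- cohort_panel(
    panel$records[, c(ID_COLS, features), drop = FALSE], clock_registry,
    provenance = panel$provenance, validate = FALSE)

  # --- imputation ----------------------------------------------------
  say("neighbor filling + split-wise PMM imputation")
  nf <- neighbor_fill(cpanel, derive_seed(seed, "neighbor_fill"))
  plan <- make_splits(nf$panel, n_splits = config$n_splits,
                      seed = derive_seed(seed, "splits"))
  sets <- build_imputed_sets(nf$panel, plan, m = config$m,
                             k_donors = config$k_donors,
                             n_burn = config$n_burn,
                             seed = derive_seed(seed, "impute"))
  for (i in seq_along(sets)) {
    std <- standardize_pair(sets[[i]]$train_table, sets[[i]]$test_table,
                            clock_registry, scope = config$standardize_scope)
    sets[[i]]$train_table <- std$train
    sets[[i]]$test_table <- std$test
  }

  # --- clock ---------------------------------------------------------
  p <- length(features)
  grid <- config$mtry_grid
  if (is.null(grid))
    grid <- unique(pmax(1L, as.integer(floor(p * c(1 / 6, 1 / 3, 2 / 3)))))
  split0 <- Filter(function(s) s$split_index == 0L, sets)
  say("tuning mtry on split-0 training sets")
  mtry <- tune_mtry(split0, features, grid, ntree = config$tune_ntree,
                    seed = derive_seed(seed, "tune"))
  say(sprintf("mtry = %d; training %d forests (ntree = %d)", mtry,
              length(sets), config$ntree))
  models <- lapply(sets, train_clock, features = features, mtry = mtry,
                   ntree = config$ntree, seed = derive_seed(seed, "clock"))
  preds <- predict_panel(models, sets)
  metrics <- clock_metrics(preds)
  rel <- relative_age(preds)
  preds <- rel$preds
  rpt <- repeatability(preds)

  # --- survival ------------------------------------------------------
  first_obs <- stats::aggregate(age_start ~ individual_id,
                                data = panel$records, FUN = min)
  names(first_obs)[2] <- "age"
  life <- build_lifetime_records(rel$lifetime, vitals,
                                 first_observed = first_obs)
  cox_lifetime <- fit_cox(life, "lifetime_relative_age")
  annual <- build_annual_records(preds, vitals)
  cox_annual <- fit_cox(annual, "relative_age", cluster = "individual_id")

  # --- adversity -----------------------------------------------------
  adv_out <- NULL
  if (!is.null(adversity)) {
    scored <- cumulative_adversity(adversity)
    conditions <- panel$records[, c("individual_id", "year_index",
                                    "rank_prop", "group_size",
                                    "rain_anomaly")]
    lmm <- fit_delta_age_lmm(preds, scored$profiles, conditions,
                             mode = "cumulative")
    coxadv <- fit_cox_with_adversity(life, scored$profiles)
    adv_out <- list(scored = scored, lmm = lmm, cox = coxadv)
  }

  # --- restricted clock ----------------------------------------------
  restricted <- NULL
  if (config$restricted) {
    ml <- registry_mortality_linked(panel$registry)
    rfeat <- setdiff(features, names(ml)[ml])
    if (length(rfeat) >= 2L && length(rfeat) < length(features)) {
      say("fitting restricted clock")
      rmodels <- lapply(sets, train_clock, features = rfeat, mtry =
                          min(mtry, length(rfeat)), ntree = config$ntree,
                        seed = derive_seed(seed, "restricted"))
      rpreds <- predict_panel(rmodels, sets)
      rrel <- relative_age(rpreds)
      rlife <- build_lifetime_records(rrel$lifetime, vitals,
                                      first_observed = first_obs)
      restricted <- list(
        features = rfeat, preds = rrel$preds,
        metrics = clock_metrics(rpreds),
        cor_with_full = stats::cor(preds$predicted_age,
                                   rpreds$predicted_age),
        cox_lifetime = fit_cox(rlife, "lifetime_relative_age"))
    }
  }

  out <- list(config = config, panel = panel, filter_report = flt$report,
              screen = screen, features = features, fill_log = nf$log,
              plan = plan, sets = sets, mtry = mtry, models = models,
              preds = preds, metrics = metrics, relative = rel,
              repeatability = rpt, vitals = vitals,
              cox_lifetime = cox_lifetime, cox_annual = cox_annual,
              adversity = adv_out, restricted = restricted, truth = truth)
  out$manifest <- pipeline_manifest(out)
  if (!is.null(config$out_dir)) write_pipeline_artifacts(out)
  out
}

pipeline_manifest <- function(res) {
  cfg <- res$config
  list(package = "npbclock",
       version = as.character(utils::packageVersion("npbclock")),
       seed = cfg$seed,
       n_records = nrow(res$panel$records),
       n_individuals = length(unique(res$panel$records$individual_id)),
       n_features = length(res$features),
       n_imputed_sets = length(res$sets),
       n_splits = cfg$n_splits, m = cfg$m,
       ntree = cfg$ntree, mtry = res$mtry,
       restricted = !is.null(res$restricted),
       files = c("predictions.csv", "metrics.json", "cox_results.json",
                 if (!is.null(res$screen)) "screen_results.csv",
                 if (!is.null(res$adversity)) "lmm_results.json",
                 if (!is.null(res$restricted)) "predictions_restricted.csv"))
}

write_pipeline_artifacts <- function(res) {
  dir.create(res$config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(res$config$out_dir, f)
  utils::write.csv(res$preds, p("predictions.csv"), row.names = FALSE)
  jsonlite::write_json(
    c(res$metrics, list(repeatability = res$repeatability)),
    p("metrics.json"), auto_unbox = TRUE, digits = NA)
  cox <- list(lifetime = res$cox_lifetime$results,
              annual = res$cox_annual$results)
  if (!is.null(res$adversity))
    cox$lifetime_with_adversity <- res$adversity$cox$joint$results
  jsonlite::write_json(cox, p("cox_results.json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(res$screen))
    utils::write.csv(res$screen$results, p("screen_results.csv"),
                     row.names = FALSE)
  if (!is.null(res$adversity))
    jsonlite::write_json(res$adversity$lmm$coefficients,
                         p("lmm_results.json"), auto_unbox = TRUE,
                         digits = NA)
  if (!is.null(res$restricted))
    utils::write.csv(res$restricted$preds, p("predictions_restricted.csv"),
                     row.names = FALSE)
  jsonlite::write_json(res$manifest, p("manifest.json"), auto_unbox = TRUE)
  invisible(res$config$out_dir)
}

#' Replicated simulation study
#'
#' Repeats simulate -> pipeline over fresh seeds and reports, per
#' replicate: clock R^2, compression slope, the correlation of lifetime
#' relative age with true frailty, the lifetime relative-age hazard ratio
#' and its p-value, and the cumulative-adversity LMM coefficient. Intended
#' for scaled-down configurations.
#'
#' @param config A [pipeline_config()] with `sim` set.
#' @param n_replicates Number of replicates (>= 1).
#' @return List with per-replicate data.frame `replicates` and a `summary`
#'   row of means (plus Monte-Carlo standard errors when n > 1).
#' @export
run_simulation_study <- function(config, n_replicates = 1L) {
  stopifnot(n_replicates >= 1L, !is.null(config$sim))
  rows <- lapply(seq_len(n_replicates), function(r) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, "replicate", r)
    cfg$out_dir <- NULL
    res <- run_pipeline(cfg)
    fr <- res$truth$frailty[match(res$relative$lifetime$individual_id,
                                  res$truth$individual_id)]
    hr <- res$cox_lifetime$results
    adv_b <- if (!is.null(res$adversity)) {
      cc <- res$adversity$lmm$coefficients
      cc$estimate[cc$term == "cumulative_index"]
    } else NA_real_
    data.frame(replicate = r, r_squared = res$metrics$r_squared,
               slope = res$metrics$slope_pred_vs_known,
               frailty_cor = stats::cor(res$relative$lifetime$lifetime_relative_age, fr),
               hr = hr$hazard_ratio[1], hr_p = hr$p_value[1],
               adversity_beta = adv_b)
  })
  reps <- do.call(rbind, rows)
  num <- reps[, setdiff(names(reps), "replicate")]
  summary <- data.frame(stat = names(num),
                        mean = colMeans(num, na.rm = TRUE),
                        mc_se = if (n_replicates > 1)
                          apply(num, 2, stats::sd) / sqrt(n_replicates)
                        else NA_real_,
                        row.names = NULL)
  list(replicates = reps, summary = summary)
}
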