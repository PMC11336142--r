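ID_COLS <- c("individual_id", "year_index", "age_start", "observation_days")

#' Cohort panel
#'
#' A long-format panel of individual-year records: one row per individual
#' per year of adult life, carrying chronological age at the start of the
#' year, observation effort in days, the trait columns declared in the
#' registry, and (optionally) extra per-year covariate columns such as
#' current social or environmental conditions.
#'
#' @param records A data.frame with columns `individual_id`, `year_index`,
#'   `age_start`, `observation_days`, one column per registry trait, and any
#'   declared covariate columns. Missing trait values are `NA`.
#' @param registry A [trait_registry()].
#' @param covariates Character vector of non-trait covariate column names
#'   present in `records`.
#' @param provenance Free-text provenance string.
#' @param validate Run invariant checks (default `TRUE`).
#' @return An object of class `cohort_panel`.
#' @export
cohort_panel <- function(records, registry, covariates = character(),
                         provenance = "", validate = TRUE) {
  stopifnot(is.data.frame(records))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  obj <- structure(
    list(records = records, registry = registry,
         covariates = as.character(covariates), provenance = provenance),
    class = "cohort_panel"
  )
  if (validate) validate_panel(obj)
  obj
}

#' @export
print.cohort_panel <- function(x, ...) {
  cat("<cohort_panel> ", nrow(x$records), " individual-years, ",
      length(unique(x$records$individual_id)), " individuals, ",
      length(x$registry), " traits\n", sep = "")
  if (nzchar(x$provenance)) cat("  provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Panel trait names
#' @param panel A `cohort_panel`.
#' @export
panel_traits <- function(panel) registry_names(panel$registry)

#' Panel trait matrix (traits only, canonical registry order)
#' @param panel A `cohort_panel`.
#' @export
panel_trait_matrix <- function(panel) {
  as.matrix(panel$records[, panel_traits(panel), drop = FALSE])
}

validate_panel <- function(panel) {
  rec <- panel$records
  miss_cols <- setdiff(ID_COLS, names(rec))
  if (length(miss_cols))
    stop("panel records missing required columns: ",
         paste(miss_cols, collapse = ", "))
  traits <- panel_traits(panel)
  extra <- setdiff(names(rec), c(ID_COLS, traits, panel$covariates))
  if (length(extra))
    stop("schema error: columns not in trait registry or covariates: ",
         paste(extra, collapse = ", "))
  absent <- setdiff(traits, names(rec))
  if (length(absent))
    stop("schema error: registry traits absent from records: ",
         paste(absent, collapse = ", "))
  key <- paste(rec$individual_id, rec$year_index, sep = "\r")
  if (anyDuplicated(key)) {
    d <- rec[duplicated(key), c("individual_id", "year_index"), drop = FALSE]
    stop("integrity error: duplicate (individual_id, year_index): ",
         paste(sprintf("(%s, %s)", d$individual_id, d$year_index),
               collapse = "; "))
  }
  kinds <- registry_kinds(panel$registry)
  for (tr in traits) {
    v <- rec[[tr]]
    obs <- v[!is.na(v)]
    bad <- switch(kinds[[tr]],
      continuous   = !is.numeric(v),
      binary       = length(obs) && !all(obs %in% c(0, 1)),
      categorical3 = length(obs) && !all(obs %in% c(1, 2, 3)))
    if (isTRUE(bad))
      stop("schema error: trait '", tr, "' violates kind '", kinds[[tr]], "'")
  }
  if (any(!is.na(rec$age_start) & rec$age_start < 4))
    stop("integrity error: age_start below adult onset (4.0)")
  if (any(rec$observation_days < 0, na.rm = TRUE))
    stop("integrity error: negative observation_days")
  invisible(panel)
}

#' Read a cohort panel from CSV
#'
#' Expects columns `individual_id, year_index, age_start, observation_days`
#' followed by trait columns named in the registry (and optionally declared
#' covariate columns). Missing values are empty fields or `NA`.
#'
#' @param source Path to a CSV file, or a connection.
#' @param registry A [trait_registry()] describing the trait columns.
#' @param covariates Names of permitted extra covariate columns.
#' @param provenance Provenance string stored on the panel.
#' @return A validated `cohort_panel`.
#' @export
read_panel <- function(source, registry, covariates = character(),
                       provenance = paste0("read_panel:",
                                           if (is.character(source)) source else "<connection>")) {
  rec <- utils::read.csv(source, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  cohort_panel(rec, registry, covariates = covariates,
               provenance = provenance)
}

#' Write a cohort panel to CSV
#'
#' Inverse of [read_panel()]: `read_panel(write_panel(p), p$registry)` is
#' the identity on valid panels at the written precision.
#'
#' @param panel A `cohort_panel`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(panel$records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Apply the study inclusion filters
#'
#' Drops individual-years observed for fewer than `min_days` days and
#' individual-years where at least `max_missing` of the clock traits are
#' missing (the default reproduces the >= 65% missingness rule: with 49
#' traits, >= 32 missing).
#'
#' @param panel A `cohort_panel` restricted to the clock traits.
#' @param min_days Minimum observation days (records with fewer are dropped).
#' @param max_missing Records with at least this many missing clock traits
#'   are dropped. Default `ceiling(0.65 * n_traits)`.
#' @return A list with elements `panel` (filtered) and `report` (a
#'   data.frame of dropped records with a `reason` column).
#' @export
apply_inclusion_filters <- function(panel, min_days = 60L,
                                    max_missing = NULL) {
  traits <- panel_traits(panel)
  if (is.null(max_missing)) max_missing <- ceiling(0.65 * length(traits))
  rec <- panel$records
  n_miss <- rowSums(is.na(rec[, traits, drop = FALSE]))
  low_days <- rec$observation_days < min_days
  too_missing <- n_miss >= max_missing
  drop <- low_days | too_missing
  reason <- ifelse(low_days & too_missing, "low_days+missingness",
                   ifelse(low_days, "low_days", "missingness"))
  report <- data.frame(individual_id = rec$individual_id[drop],
                       year_index = rec$year_index[drop],
                       observation_days = rec$observation_days[drop],
                       n_missing = n_miss[drop],
                       reason = reason[drop],
                       stringsAsFactors = FALSE)
  out <- cohort_panel(rec[!drop, , drop = FALSE], panel$registry,
                      covariates = panel$covariates,
                      provenance = panel$provenance, validate = FALSE)
  list(panel = out, report = report)
}

#' Annualize sample-level residuals
#'
#' Traits measured at the level of individual samples (hormone metabolite
#' concentrations, parasite counts) are converted to annual trait values by
#' regressing the raw values on nuisance covariates and averaging the
#' residuals within each individual-year. Years with no samples yield `NA`.
#'
#' @param measures A data.frame with columns `individual_id`,
#'   `collection_age` (years), `value`, plus any covariate columns used by
#'   `covariate_model`.
#' @param covariate_model A one-sided formula naming the covariates, e.g.
#'   `~ 1` (intercept only) or `~ season + hydro_year`.
#' @param entry_age Adult entry age used to map `collection_age` to a
#'   `year_index` (`floor(collection_age - entry_age)`).
#' @return A data.frame `individual_id, year_index, value` with one row per
#'   contributing individual-year (mean residual).
#' @export
annualize_sample_residuals <- function(measures, covariate_model = ~ 1,
                                       entry_age = 4) {
  stopifnot(is.data.frame(measures),
            all(c("individual_id", "collection_age", "value") %in%
                  names(measures)))
  vars <- all.vars(covariate_model)
  absent <- setdiff(vars, names(measures))
  if (length(absent))
    stop("covariate_model names covariates absent from measures: ",
         paste(absent, collapse = ", "))
  f <- stats::as.formula(paste("value ~", paste(deparse(covariate_model[[2]]),
                                                collapse = " ")))
  fit <- tryCatch(stats::lm(f, data = measures),
                  error = function(e) stop("model error: ", conditionMessage(e)))
  if (any(is.na(stats::coef(fit))))
    stop("model error: covariate model is rank-deficient")
  res <- stats::residuals(fit)
  yi <- floor(measures$collection_age - entry_age)
  agg <- stats::aggregate(res,
                          by = list(individual_id = measures$individual_id,
                                    year_index = yi),
                          FUN = mean)
  names(agg)[3] <- "value"
  agg[order(agg$individual_id, agg$year_index), , drop = FALSE]
}

#' Center and standardize continuous traits
#'
#' Continuous traits are transformed to `(value - location) / scale`. When
#' `stats` is `NULL`, location is the trait mean and scale its sample
#' standard deviation (n - 1 denominator), computed over observed cells and
#' returned so that test partitions can be standardized with training-set
#' statistics. Binary and categorical traits pass through unchanged.
#' Zero-variance traits are centered only (scale fixed at 1) and flagged.
#'
#' @param panel A `cohort_panel`.
#' @param stats Optional data.frame `trait, location, scale` as returned by
#'   a previous call (applied as-is).
#' @return List with `panel` (standardized) and `stats` (data.frame with
#'   columns `trait, location, scale, sd_convention, zero_variance`).
#' @export
standardize_traits <- function(panel, stats = NULL) {
  kinds <- registry_kinds(panel$registry)
  cont <- names(kinds)[kinds == "continuous"]
  rec <- panel$records
  if (is.null(stats)) {
    loc <- vapply(cont, function(tr) mean(rec[[tr]], na.rm = TRUE), 0)
    sc <- vapply(cont, function(tr) stats::sd(rec[[tr]], na.rm = TRUE), 0)
    zero <- !is.finite(sc) | sc <= 0
    sc[zero] <- 1
    loc[!is.finite(loc)] <- 0
    stats <- data.frame(trait = cont, location = unname(loc),
                        scale = unname(sc),
                        sd_convention = "sample (n-1)",
                        zero_variance = unname(zero),
                        stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("trait", "location", "scale") %in% names(stats)))
    absent <- setdiff(cont, stats$trait)
    if (length(absent))
      stop("supplied stats missing traits: ", paste(absent, collapse = ", "))
  }
  for (i in seq_len(nrow(stats))) {
    tr <- stats$trait[i]
    if (tr %in% names(rec))
      rec[[tr]] <- (rec[[tr]] - stats$location[i]) / stats$scale[i]
  }
  out <- cohort_panel(rec, panel$registry, covariates = panel$covariates,
                      provenance = panel$provenance, validate = FALSE)
  list(panel = out, stats = stats)
}
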