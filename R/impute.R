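#' Phase-1 neighbor filling of adjacent years
#'
#' Fills a missing trait cell from the same individual's immediately
#' adjacent years, using only originally observed values (fills never
#' propagate). With both neighbors observed: continuous traits get their
#' mean, non-continuous traits a random choice between the two (seeded).
#' With one neighbor observed, its value is carried.
#'
#' @param panel A `cohort_panel` that passed the inclusion filters.
#' @param seed Integer seed for the random neighbor choice.
#' @return List with `panel` (filled) and `log` (data.frame of filled
#'   cells: `individual_id, year_index, trait, source, value`; `source` in
#'   `"before"`, `"after"`, `"mean"`, `"random_before"`, `"random_after"`).
#' @export
neighbor_fill <- function(panel, seed = 1L) {
  set.seed(seed)
  rec <- panel$records
  ord <- order(rec$individual_id, rec$year_index)
  rec <- rec[ord, , drop = FALSE]
  traits <- panel_traits(panel)
  kinds <- registry_kinds(panel$registry)
  ids <- rec$individual_id
  yi <- rec$year_index
  n <- nrow(rec)
  # neighbor row indices: previous/next row iff same individual and
  # year_index differs by exactly 1
  prev_ok <- c(FALSE, ids[-1] == ids[-n] & yi[-1] == yi[-n] + 1L)
  next_ok <- c(ids[-n] == ids[-1] & yi[-n] == yi[-1] - 1L, FALSE)
  logs <- list()
  for (tr in traits) {
    v <- rec[[tr]]
    miss <- which(is.na(v))
    if (!length(miss)) next
    vb <- ifelse(prev_ok, c(NA, v[-n]), NA)  # originally observed neighbors
    va <- ifelse(next_ok, c(v[-1], NA), NA)
    for (i in miss) {
      b <- vb[i]; a <- va[i]
      if (is.na(b) && is.na(a)) next
      if (!is.na(b) && !is.na(a)) {
        if (kinds[[tr]] == "continuous") {
          val <- (b + a) / 2; src <- "mean"
        } else if (stats::runif(1) < 0.5) {
          val <- b; src <- "random_before"
        } else {
          val <- a; src <- "random_after"
        }
      } else if (!is.na(b)) {
        val <- b; src <- "before"
      } else {
        val <- a; src <- "after"
      }
      rec[[tr]][i] <- val
      logs[[length(logs) + 1L]] <- data.frame(
        individual_id = ids[i], year_index = yi[i], trait = tr,
        source = src, value = val, stringsAsFactors = FALSE)
    }
  }
  log <- if (length(logs)) do.call(rbind, logs) else
    data.frame(individual_id = character(), year_index = integer(),
               trait = character(), source = character(), value = numeric(),
               stringsAsFactors = FALSE)
  out <- cohort_panel(rec, panel$registry, covariates = panel$covariates,
                      provenance = panel$provenance, validate = FALSE)
  list(panel = out, log = log)
}

#' Build the train/test split plan
#'
#' Assigns every individual-year to exactly one test fold so that each
#' individual's years are spread as evenly as possible across folds
#' (per-individual fold counts differ by at most 1): the individual's years
#' are taken in year order and dealt round-robin into a randomly permuted,
#' randomly rotated fold order.
#'
#' @param panel A `cohort_panel`.
#' @param n_splits Number of folds (default 5).
#' @param seed Integer seed.
#' @return A `split_plan`: list with `n_splits` and `assignment`
#'   (data.frame `individual_id, year_index, fold` with fold in
#'   `0..n_splits-1`).
#' @export
make_splits <- function(panel, n_splits = 5L, seed = 1L) {
  stopifnot(n_splits >= 2L)
  set.seed(seed)
  rec <- panel$records[order(panel$records$individual_id,
                             panel$records$year_index), ]
  pieces <- lapply(split(seq_len(nrow(rec)), rec$individual_id), function(ix) {
    fold_order <- sample(n_splits) - 1L
    off <- sample.int(n_splits, 1L) - 1L
    folds <- fold_order[((seq_along(ix) - 1L + off) %% n_splits) + 1L]
    data.frame(individual_id = rec$individual_id[ix],
               year_index = rec$year_index[ix], fold = folds,
               stringsAsFactors = FALSE)
  })
  assignment <- do.call(rbind, pieces)
  rownames(assignment) <- NULL
  structure(list(n_splits = as.integer(n_splits), assignment = assignment),
            class = "split_plan")
}

# one-hot expansion of the predictor side; categorical/binary columns
# enter other columns' regressions as indicators
pmm_predictor_matrix <- function(tab, kinds, exclude) {
  cols <- setdiff(names(tab), exclude)
  mats <- lapply(cols, function(cn) {
    v <- tab[[cn]]
    if (kinds[[cn]] == "categorical3") {
      m <- cbind(as.numeric(v == 2), as.numeric(v == 3))
      colnames(m) <- paste0(cn, c("_2", "_3"))
      m
    } else matrix(v, ncol = 1, dimnames = list(NULL, cn))
  })
  cbind(`(Intercept)` = 1, do.call(cbind, mats))
}

pmm_draw_donor <- function(pred_miss, pred_obs, obs_values, k_donors) {
  k <- min(k_donors, length(pred_obs))
  vapply(pred_miss, function(p) {
    d <- abs(pred_obs - p)
    near <- order(d)[seq_len(k)]          # ties broken by row order
    w <- 1 / (seq_len(k) + 1)             # rank weighting, rank 1 closest
    obs_values[near[sample.int(k, 1L, prob = w / sum(w))]]
  }, numeric(1))
}

#' Chained predictive mean matching
#'
#' Multiple imputation of a trait table by chained-equations PMM. Missing
#' cells are initialized at the column median (continuous) or mode
#' (binary/categorical); then for `n_burn` sweeps each incomplete column is
#' regressed (linearly, with one-hot categorical predictors) on all other
#' columns, predictions are computed for every row, and each missing cell
#' draws a donor among the `k_donors` observed rows with closest
#' predictions, with probability proportional to `1/(rank + 1)`. Imputed
#' values are therefore always observed values of the same column. Age is
#' never part of the predictor matrix (the table must not contain it).
#'
#' @param table Data.frame of trait columns only (no id or age columns).
#' @param kinds Named character vector of trait kinds for the columns.
#' @param m Number of independent imputations (chains).
#' @param k_donors Donor pool size.
#' @param n_burn Chained sweeps per imputation.
#' @param seed Integer seed; chain `j` uses a seed derived from it.
#' @return List of `m` completed data.frames.
#' @export
pmm_impute <- function(table, kinds, m = 5L, k_donors = 5L, n_burn = 3L,
                       seed = 1L) {
  stopifnot(is.data.frame(table))
  miss_cols <- names(table)[vapply(table, anyNA, logical(1))]
  for (cn in miss_cols) {
    n_obs <- sum(!is.na(table[[cn]]))
    if (n_obs == 0L)
      stop("imputation error: column '", cn, "' entirely missing")
    if (n_obs < k_donors)
      stop("imputation error: column '", cn, "' has fewer than k_donors (",
           k_donors, ") observed values")
  }
  if (!length(miss_cols)) return(replicate(m, table, simplify = FALSE))
  miss_idx <- lapply(table[miss_cols], function(v) which(is.na(v)))
  lapply(seq_len(m), function(chain) {
    set.seed(derive_seed(seed, "pmm_chain", chain))
    tab <- table
    for (cn in miss_cols) {                  # initialization
      v <- tab[[cn]]
      obs <- v[!is.na(v)]
      init <- if (kinds[[cn]] == "continuous") stats::median(obs) else
        as.numeric(names(sort(table(obs), decreasing = TRUE))[1])
      v[is.na(v)] <- init
      tab[[cn]] <- v
    }
    for (sweep in seq_len(n_burn)) {
      for (cn in miss_cols) {
        mi <- miss_idx[[cn]]
        X <- pmm_predictor_matrix(tab, kinds, exclude = cn)
        oi <- setdiff(seq_len(nrow(tab)), mi)
        y_obs <- table[[cn]][oi]
        fit <- stats::lm.fit(X[oi, , drop = FALSE], y_obs)
        beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
        pred <- drop(X %*% beta)
        tab[[cn]][mi] <- pmm_draw_donor(pred[mi], pred[oi], y_obs, k_donors)
      }
    }
    tab
  })
}

#' Build the split-by-imputation completed data sets
#'
#' For each train/test split, runs [pmm_impute()] on the training rows and
#' on the test rows separately (no information flows across the partition),
#' `m` times each, and pairs the results by imputation index, yielding
#' `n_splits * m` completed train/test set pairs.
#'
#' @param panel A neighbor-filled `cohort_panel`.
#' @param plan A `split_plan` from [make_splits()].
#' @param m Imputations per split.
#' @param k_donors,n_burn Passed to [pmm_impute()].
#' @param seed Integer seed.
#' @return List of `n_splits * m` imputed sets, each a list with
#'   `split_index`, `imputation_index`, `train_table`, `test_table` (both
#'   completed data.frames carrying id columns, `age_start` and the traits).
#' @export
build_imputed_sets <- function(panel, plan, m = 5L, k_donors = 5L,
                               n_burn = 3L, seed = 1L) {
  rec <- panel$records
  traits <- panel_traits(panel)
  kinds <- registry_kinds(panel$registry)
  key <- paste(rec$individual_id, rec$year_index, sep = "\r")
  akey <- paste(plan$assignment$individual_id, plan$assignment$year_index,
                sep = "\r")
  fold <- plan$assignment$fold[match(key, akey)]
  if (anyNA(fold))
    stop("plan integrity error: panel records missing from split plan")
  sets <- list()
  for (s in seq_len(plan$n_splits) - 1L) {
    test_rows <- which(fold == s)
    train_rows <- which(fold != s)
    tr_imp <- pmm_impute(rec[train_rows, traits, drop = FALSE], kinds,
                         m = m, k_donors = k_donors, n_burn = n_burn,
                         seed = derive_seed(seed, "train", s))
    te_imp <- pmm_impute(rec[test_rows, traits, drop = FALSE], kinds,
                         m = m, k_donors = k_donors, n_burn = n_burn,
                         seed = derive_seed(seed, "test", s))
    for (j in seq_len(m)) {
      mk <- function(rows, imp) cbind(
        rec[rows, c("individual_id", "year_index", "age_start"),
            drop = FALSE],
        imp, row.names = NULL)
      sets[[length(sets) + 1L]] <- list(
        split_index = s, imputation_index = j - 1L,
        train_table = mk(train_rows, tr_imp[[j]]),
        test_table = mk(test_rows, te_imp[[j]]))
    }
  }
  sets
}
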