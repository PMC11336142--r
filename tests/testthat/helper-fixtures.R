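# Shared fixtures: tiny registries and panels built in code.

tiny_registry <- function() {
  trait_registry(
    trait_spec("ct_a", "continuous", "activity_budget"),
    trait_spec("ct_b", "continuous", "endocrine", mortality_linked = TRUE),
    trait_spec("bt_a", "binary", "illness_injury"),
    trait_spec("mt_a", "categorical3", "dominance_rank"))
}

tiny_panel <- function(registry = tiny_registry()) {
  rec <- data.frame(
    individual_id = c("F001", "F001", "F001", "F002", "F002"),
    year_index = c(0L, 1L, 2L, 0L, 1L),
    age_start = c(4, 5, 6, 4, 5),
    observation_days = c(200L, 250L, 180L, 300L, 90L),
    ct_a = c(1.5, 2.5, NA, 0.5, 1.0),
    ct_b = c(0.1, NA, 0.3, -0.2, 0.0),
    bt_a = c(0L, 1L, NA, 0L, 0L),
    mt_a = c(1, 2, 3, NA, 2),
    stringsAsFactors = FALSE)
  cohort_panel(rec, registry)
}

# small cohort for medium-weight tests
small_sim <- function(n_individuals = 60L, ...) {
  sim_config(n_individuals = n_individuals, n_continuous = 6L, n_binary = 1L,
             n_categorical3 = 1L, ...)
}

expect_setequal_rows <- function(a, b) {
  expect_equal(a[order(a$individual_id, a$year_index), , drop = FALSE],
               b[order(b$individual_id, b$year_index), , drop = FALSE],
               ignore_attr = TRUE)
}
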