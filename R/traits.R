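#' Trait specification
#'
#' A trait specification records everything downstream stages need to know
#' about one clock trait: its measurement kind (which determines the
#' screening model family), its category label, the candidate covariates for
#' the screening base model, and whether the trait is already known to
#' predict mortality (such traits are excluded from the restricted clock
#' variant).
#'
#' @param name Trait identifier (syntactic column name).
#' @param kind One of `"continuous"`, `"binary"`, `"categorical3"`.
#' @param category Free-form category label (e.g. `"activity_budget"`).
#' @param candidate_covariates Character vector of covariate column names to
#'   consider in the AIC base-model search (at most 10).
#' @param mortality_linked Logical; `TRUE` marks the trait for exclusion
#'   from the restricted clock.
#' @return An object of class `trait_spec`.
#' @export
trait_spec <- function(name, kind = c("continuous", "binary", "categorical3"),
                       category = "uncategorized",
                       candidate_covariates = character(),
                       mortality_linked = FALSE) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (length(candidate_covariates) > 10L)
    stop("at most 10 candidate covariates are supported (exhaustive search)")
  structure(
    list(name = name, kind = kind, category = category,
         candidate_covariates = as.character(candidate_covariates),
         mortality_linked = isTRUE(mortality_linked)),
    class = "trait_spec"
  )
}

#' Trait registry
#'
#' An ordered collection of [trait_spec()] objects. Registry order is the
#' canonical trait order used by the screen, the imputer and the clock.
#'
#' @param ... `trait_spec` objects, or a single list of them.
#' @return An object of class `trait_registry`.
#' @export
trait_registry <- function(...) {
  specs <- list(...)
  if (length(specs) == 1L && !inherits(specs[[1L]], "trait_spec"))
    specs <- specs[[1L]]
  ok <- vapply(specs, inherits, logical(1), "trait_spec")
  if (!all(ok)) stop("all registry entries must be trait_spec objects")
  nm <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate trait names in registry: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  names(specs) <- nm
  structure(specs, class = "trait_registry")
}

#' @export
print.trait_registry <- function(x, ...) {
  kinds <- registry_kinds(x)
  cat("<trait_registry> ", length(x), " traits (",
      sum(kinds == "continuous"), " continuous, ",
      sum(kinds == "binary"), " binary, ",
      sum(kinds == "categorical3"), " categorical3); ",
      sum(registry_mortality_linked(x)), " mortality-linked\n", sep = "")
  invisible(x)
}

#' Registry accessors
#'
#' @param registry A `trait_registry`.
#' @return `registry_names()` the trait names in canonical order;
#'   `registry_kinds()` a named character vector of kinds;
#'   `registry_mortality_linked()` a named logical vector.
#' @export
registry_names <- function(registry) {
  vapply(registry, `[[`, character(1), "name")
}

#' @rdname registry_names
#' @export
registry_kinds <- function(registry) {
  k <- vapply(registry, `[[`, character(1), "kind")
  names(k) <- registry_names(registry)
  k
}

#' @rdname registry_names
#' @export
registry_mortality_linked <- function(registry) {
  m <- vapply(registry, `[[`, logical(1), "mortality_linked")
  names(m) <- registry_names(registry)
  m
}

#' Subset a registry by trait names
#'
#' @param registry A `trait_registry`.
#' @param names Trait names to keep (canonical order is preserved).
#' @export
registry_subset <- function(registry, names) {
  keep <- registry_names(registry) %in% names
  trait_registry(unclass(registry)[keep])
}

#' Default synthetic trait registry
#'
#' Builds the registry used by the synthetic cohort at its default scale:
#' 49 traits (38 continuous, 7 binary, 4 three-level categorical) spread
#' over ten categories, with 17 traits flagged as mortality-linked (the
#' restricted-clock exclusion set).
#'
#' @param n_continuous,n_binary,n_categorical3 Trait counts per kind.
#' @param n_mortality_linked Number of traits flagged mortality-linked
#'   (assigned from the start of the registry, continuous first). Default
#'   17 at the full 49-trait scale, scaled proportionally (17/49) for
#'   smaller registries.
#' @return A `trait_registry`.
#' @export
default_registry <- function(n_continuous = 38L, n_binary = 7L,
                             n_categorical3 = 4L, n_mortality_linked = NULL) {
  categories <- c("activity_budget", "endocrine", "illness_injury",
                  "parasites", "reproduction", "maternal_care",
                  "social_integration", "dyadic_sociality", "agonism",
                  "dominance_rank")
  nm <- c(sprintf("ct_%02d", seq_len(n_continuous)),
          sprintf("bt_%02d", seq_len(n_binary)),
          sprintf("mt_%02d", seq_len(n_categorical3)))
  kind <- rep(c("continuous", "binary", "categorical3"),
              c(n_continuous, n_binary, n_categorical3))
  n <- length(nm)
  if (is.null(n_mortality_linked))
    n_mortality_linked <- round(n * 17 / 49)
  if (n_mortality_linked > n) stop("more mortality-linked traits than traits")
  ml <- seq_len(n) <= n_mortality_linked
  specs <- lapply(seq_len(n), function(i) {
    trait_spec(nm[i], kind[i],
               category = categories[((i - 1L) %% length(categories)) + 1L],
               mortality_linked = ml[i])
  })
  trait_registry(specs)
}
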