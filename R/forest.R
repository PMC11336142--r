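#' Fit a regression random forest
#'
#' Bootstrap-aggregated CART regression trees with variance-reduction
#' splits and `mtry` feature subsampling (the standard regression random
#' forest). Implemented in C++; deterministic for a fixed seed.
#'
#' @param x Numeric feature matrix (binary and 3-level categorical traits
#'   enter as their numeric codes).
#' @param y Numeric response (chronological age).
#' @param ntree Number of trees (default 2000).
#' @param mtry Features sampled per split (default `floor(ncol(x)/3)`,
#'   the regression convention).
#' @param min_node Stop splitting nodes at or below this size (default 5).
#' @param seed Integer seed.
#' @return An `npb_forest`: list with the serialized trees, out-of-bag
#'   predictions (`oob`), and the fit parameters.
#' @export
rf_regression <- function(x, y, ntree = 2000L, mtry = NULL, min_node = 5L,
                          seed = 1L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("integrity error: feature matrix contains missing cells")
  if (!is.numeric(y) || anyNA(y)) stop("integrity error: non-numeric response")
  if (is.null(mtry)) mtry <- max(1L, floor(ncol(x) / 3))
  fit <- .rf_fit(x, as.numeric(y), as.integer(ntree), as.integer(mtry),
                 as.integer(min_node), as.double(seed))
  fit$features <- colnames(x)
  class(fit) <- "npb_forest"
  fit
}

#' @export
predict.npb_forest <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$features) && !is.null(colnames(newdata)))
    newdata <- newdata[, object$features, drop = FALSE]
  storage.mode(newdata) <- "double"
  if (anyNA(newdata)) stop("integrity error: newdata contains missing cells")
  .rf_predict(object$trees, newdata)
}

#' @export
print.npb_forest <- function(x, ...) {
  cat("<npb_forest> ", x$ntree, " trees, mtry ", x$mtry, ", ",
      length(x$features), " features\n", sep = "")
  invisible(x)
}
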