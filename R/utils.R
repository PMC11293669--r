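#' @keywords internal
"_PACKAGE"

## logistic sigmoid; plogis is numerically stable at large |z|
sigmoid <- function(z) stats::plogis(z)

## set the RNG only when a seed is supplied, so callers can manage
## randomness globally if they prefer
seed_rng <- function(seed) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

## columns holding features in a cohort table: f01, f02, ...
feature_columns <- function(table) {
  cols <- grep("^f[0-9]+$", names(table), value = TRUE)
  if (length(cols) == 0L)
    stop("no feature columns (expected names matching '^f[0-9]+$')")
  cols
}

#' Extract the feature matrix of a cohort table
#'
#' Returns the numeric matrix of the `f01..fNN` feature columns.
#'
#' @param table A cohort `data.frame`.
#' @return A numeric matrix.
#' @export
feature_matrix <- function(table) {
  as.matrix(table[, feature_columns(table), drop = FALSE])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
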