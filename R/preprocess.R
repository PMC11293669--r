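#' Fit a min-max scaler on training features
#'
#' Records the per-feature minimum and maximum of the training rows; the
#' resulting transform maps the training range of each feature onto
#' \[0, 1\]. Values outside the fitted range are mapped linearly beyond
#' \[0, 1\] (no clipping), which keeps the transform affine and
#' differentiable for downstream gradient training.
#'
#' @param x A numeric matrix/data.frame of features, or a cohort table
#'   (feature columns `f..` are used).
#' @return An object of class `minmax_scaler`.
#' @examples
#' sc <- fit_minmax(data.frame(f01 = c(2, 4, 6)))
#' predict(sc, data.frame(f01 = c(2, 4, 6, 8)))  # 0, 0.5, 1, 1.5
#' @export
fit_minmax <- function(x) {
  x <- as_feature_mat(x)
  mins <- apply(x, 2, min)
  maxs <- apply(x, 2, max)
  degenerate <- maxs <= mins
  if (any(degenerate))
    stop("constant feature(s), degenerate scale: ",
         paste(colnames(x)[degenerate], collapse = ", "))
  structure(list(min = mins, max = maxs, features = colnames(x)),
            class = "minmax_scaler")
}

as_feature_mat <- function(x) {
  if (is.data.frame(x) && any(grepl("^f[0-9]+$", names(x))))
    x <- x[, feature_columns(x), drop = FALSE]
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("features must be numeric")
  if (is.null(colnames(x))) colnames(x) <- sprintf("f%02d", seq_len(ncol(x)))
  x
}

#' Apply (or invert) a fitted min-max scaler
#'
#' @param object A `minmax_scaler`.
#' @param newdata Features to transform (matrix, data.frame or cohort table).
#' @param inverse If `TRUE`, map scaled values back to the original units.
#' @param ... Unused.
#' @return A numeric matrix of transformed features.
#' @export
predict.minmax_scaler <- function(object, newdata, inverse = FALSE, ...) {
  x <- as_feature_mat(newdata)
  if (ncol(x) != length(object$min))
    stop("scaler fitted on ", length(object$min), " features, got ", ncol(x))
  rng <- object$max - object$min
  if (inverse)
    sweep(sweep(x, 2, rng, "*"), 2, object$min, "+")
  else
    sweep(sweep(x, 2, object$min, "-"), 2, rng, "/")
}

#' @export
print.minmax_scaler <- function(x, ...) {
  cat("Min-max scaler on", length(x$min), "features\n")
  invisible(x)
}

#' Serialize a min-max scaler to JSON
#'
#' @param object A `minmax_scaler`.
#' @param file Optional path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `file`).
#' @export
scaler_to_json <- function(object, file = NULL) {
  stopifnot(inherits(object, "minmax_scaler"))
  js <- jsonlite::toJSON(list(min = object$min, max = object$max,
                              features = object$features), digits = NA)
  if (is.null(file)) return(js)
  writeLines(js, file)
  invisible(js)
}

#' @rdname scaler_to_json
#' @param json JSON string or path produced by [scaler_to_json()].
#' @export
scaler_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  structure(list(min = stats::setNames(as.numeric(obj$min), obj$features),
                 max = stats::setNames(as.numeric(obj$max), obj$features),
                 features = obj$features),
            class = "minmax_scaler")
}

#' Build per-subject summary vectors
#'
#' For each subject, concatenates the per-level feature means in fixed
#' level order 0..4: with 22 features this yields the 110-dimensional
#' subject vectors used for clustering. Observations are grouped by
#' rounding `pain_label` to the nearest integer level.
#'
#' @param table A (normalized) cohort table; every subject must have at
#'   least one observation at every level 0..4.
#' @return A numeric matrix, one row per subject (rownames = subject ids),
#'   `n_features * 5` columns named `f01_l0 .. fNN_l4`.
#' @export
subject_vectors <- function(table) {
  x <- feature_matrix(table)
  lev <- as.integer(round(table$pain_label))
  subs <- levels(factor(table$subject_id))
  p <- ncol(x)
  out <- matrix(NA_real_, nrow = length(subs), ncol = 5L * p,
                dimnames = list(subs,
                                paste0(rep(colnames(x), times = 5), "_l",
                                       rep(0:4, each = p))))
  for (s in seq_along(subs)) {
    for (l in 0:4) {
      rows <- table$subject_id == subs[s] & lev == l
      if (!any(rows))
        stop("subject ", subs[s], " has no observations at level ", l)
      out[s, (l * p + 1):(l * p + p)] <- colMeans(x[rows, , drop = FALSE])
    }
  }
  if (!all(is.finite(out))) stop("non-finite subject vector entries")
  out
}

#' Cross-validation fold assignment
#'
#' Partitions rows into `k` folds: each row belongs to exactly one test
#' fold, so the test sets are pairwise disjoint and their union is the
#' data. Optionally stratified so every fold sees all strata (by default
#' the rounded pain level, stabilizing coverage estimates per fold);
#' subject-level stratification is available via `stratify_by`.
#'
#' @param table Cohort table (or any data.frame with `pain_label`).
#' @param k Number of folds (default 10).
#' @param stratify_by `"level"`, `"subject"`, `"subject_level"` (their
#'   interaction, keeping every subject-by-level cell spread across folds)
#'   or `"none"`.
#' @param seed Optional integer seed.
#' @return Integer vector of fold ids (1..k), one per row.
#' @export
cv_folds <- function(table, k = 10L,
                     stratify_by = c("level", "subject", "subject_level", "none"),
                     seed = NULL) {
  stratify_by <- match.arg(stratify_by)
  n <- nrow(table)
  if (n < k) stop("fewer rows (", n, ") than folds (", k, ")")
  seed_rng(seed)
  strata <- switch(stratify_by,
                   level = as.integer(round(table$pain_label)),
                   subject = as.integer(factor(table$subject_id)),
                   subject_level = as.integer(interaction(
                     table$subject_id, round(table$pain_label), drop = TRUE)),
                   none = rep(1L, n))
  fold <- integer(n)
  offset <- 0L
  for (s in unique(strata)) {
    idx <- sample(which(strata == s))
    ## continue dealing round-robin across strata so fold sizes balance
    fold[idx] <- ((seq_along(idx) + offset - 1L) %% k) + 1L
    offset <- offset + length(idx)
  }
  fold
}

#' Train/test index pairs for k-fold cross-validation
#'
#' @inheritParams cv_folds
#' @return A list of `k` elements, each `list(train =, test =)` row indices.
#' @export
cv_splits <- function(table, k = 10L,
                      stratify_by = c("level", "subject", "subject_level", "none"),
                      seed = NULL) {
  fold <- cv_folds(table, k, stratify_by, seed)
  lapply(seq_len(k), function(f)
    list(train = which(fold != f), test = which(fold == f)))
}
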