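#' Cluster subjects by k-means on their summary vectors
#'
#' Lloyd's algorithm with Euclidean distance on the per-subject vectors
#' from [subject_vectors()]: centroids are initialized at random subject
#' rows, each subject is assigned to the nearest centroid, centroids are
#' recomputed as cluster means, and iteration stops when assignments
#' stabilize. The within-cluster sum of squares (inertia) is non-
#' increasing across iterations; the returned fit keeps the lowest-inertia
#' run of `nstart` seeded restarts. An empty cluster is re-seeded at the
#' point farthest from its centroid.
#'
#' @param vectors Numeric matrix of subject vectors (rows = subjects).
#' @param k Number of clusters (default 4; must not exceed the number of
#'   subjects).
#' @param nstart Number of random restarts.
#' @param max_iter Iteration cap per restart.
#' @param seed Optional integer seed.
#' @return An object of class `subject_clusters`: `centroids` (k x p),
#'   `cluster` (named integer vector), `inertia`, `inertia_trace`
#'   (per-iteration, winning restart), `k`.
#' @export
kmeans_subjects <- function(vectors, k = 4L, nstart = 10L, max_iter = 100L,
                            seed = NULL) {
  vectors <- as.matrix(vectors)
  n <- nrow(vectors)
  if (k > n) stop("k must not exceed the number of subjects")
  if (k < 1) stop("k must be >= 1")
  seed_rng(seed)
  best <- NULL
  for (r in seq_len(nstart)) {
    fit <- lloyd_once(vectors, k, max_iter)
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  names(best$cluster) <- rownames(vectors)
  structure(c(best, list(k = as.integer(k))), class = "subject_clusters")
}

## squared Euclidean distances of rows of x to rows of centers (n x k)
dist2_to_centers <- function(x, centers) {
  d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * x %*% t(centers)
  pmax(d2, 0)
}

lloyd_once <- function(x, k, max_iter) {
  n <- nrow(x)
  centers <- x[sample.int(n, k), , drop = FALSE]
  assign_old <- rep(0L, n)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    d2 <- dist2_to_centers(x, centers)
    assign_new <- max.col(-d2, ties.method = "first")  # nearest, lowest index
    for (c_ in seq_len(k)) {
      members <- assign_new == c_
      if (!any(members)) {
        ## empty cluster: re-seed at the point farthest from its centroid
        far <- which.max(d2[cbind(seq_len(n), assign_new)])
        centers[c_, ] <- x[far, ]
        assign_new[far] <- c_
        members <- assign_new == c_
      }
      centers[c_, ] <- colMeans(x[members, , drop = FALSE])
    }
    d2 <- dist2_to_centers(x, centers)
    assign_new <- max.col(-d2, ties.method = "first")
    trace <- c(trace, sum(d2[cbind(seq_len(n), assign_new)]))
    if (identical(assign_new, assign_old)) break
    assign_old <- assign_new
  }
  list(centroids = centers, cluster = assign_new,
       inertia = trace[length(trace)], inertia_trace = trace)
}

#' @export
print.subject_clusters <- function(x, ...) {
  cat("k-means subject clustering: k =", x$k, "| sizes",
      paste(tabulate(x$cluster, x$k), collapse = "/"),
      "| inertia", sprintf("%.4f", x$inertia), "\n")
  invisible(x)
}

#' Assign subject vectors to their nearest cluster
#'
#' Routes (new) subjects to the cluster with the nearest centroid in
#' Euclidean distance; ties go to the lowest cluster index.
#'
#' @param vectors A subject vector or matrix of vectors.
#' @param clusters A fitted [kmeans_subjects()] object.
#' @return Integer cluster ids.
#' @export
assign_subject <- function(vectors, clusters) {
  stopifnot(inherits(clusters, "subject_clusters"))
  if (is.null(dim(vectors))) vectors <- matrix(vectors, nrow = 1)
  vectors <- as.matrix(vectors)
  if (ncol(vectors) != ncol(clusters$centroids))
    stop("vector dimension ", ncol(vectors), " does not match centroids (",
         ncol(clusters$centroids), ")")
  d2 <- dist2_to_centers(vectors, clusters$centroids)
  max.col(-d2, ties.method = "first")
}

#' Within-cluster pairwise distance summaries
#'
#' All unordered pairwise Euclidean distances between subjects within each
#' cluster, summarized by mean, quartiles and an outlier count (values
#' beyond 1.5 IQR from the quartiles). A singleton cluster yields an empty
#' summary with a warning.
#'
#' @param vectors Matrix of subject vectors.
#' @param cluster Integer cluster ids (as from [kmeans_subjects()]).
#' @return A `data.frame` with one row per cluster: `cluster`, `n_subjects`,
#'   `n_pairs`, `mean`, `q1`, `median`, `q3`, `n_outliers`.
#' @export
pairwise_distance_stats <- function(vectors, cluster) {
  vectors <- as.matrix(vectors)
  ids <- sort(unique(cluster))
  rows <- lapply(ids, function(c_) {
    v <- vectors[cluster == c_, , drop = FALSE]
    if (nrow(v) < 2) {
      warning("cluster ", c_, " has fewer than 2 subjects; empty summary")
      return(data.frame(cluster = c_, n_subjects = nrow(v), n_pairs = 0L,
                        mean = NA_real_, q1 = NA_real_, median = NA_real_,
                        q3 = NA_real_, n_outliers = NA_integer_))
    }
    d <- as.numeric(stats::dist(v))
    q <- stats::quantile(d, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    out <- sum(d < q[1] - 1.5 * iqr | d > q[3] + 1.5 * iqr)
    data.frame(cluster = c_, n_subjects = nrow(v),
               n_pairs = length(d), mean = mean(d),
               q1 = q[1], median = q[2], q3 = q[3],
               n_outliers = as.integer(out))
  })
  do.call(rbind, rows)
}

#' Train cohort models under a model-building regime
#'
#' Trains interval models on a cohort table under one of three regimes:
#' `"generalized"` (one model on all rows), `"personalized"` (one model
#' per subject, trained on that subject's rows only; subjects with fewer
#' than `min_obs` rows are skipped with a warning) or `"hybrid"` (k-means
#' on the subject vectors, then one model per cluster trained on its
#' members' rows). Hybrid with `k = 1` reduces exactly to the generalized
#' regime.
#'
#' @param table A cleaned cohort table.
#' @param regime `"generalized"`, `"personalized"` or `"hybrid"`.
#' @param method Interval method passed to [pinet()].
#' @param level Nominal coverage.
#' @param k Number of clusters (hybrid only).
#' @param min_obs Minimum rows per subject for the personalized regime.
#' @param hidden,control,seed Passed to [pinet()].
#' @return An object of class `cohort_models`: `regime`, named list
#'   `models`, and for hybrid the `clusters` fit plus the global `scaler`
#'   used for the clustering vectors.
#' @export
build_cohort_models <- function(table,
                                regime = c("generalized", "personalized", "hybrid"),
                                method = "soft", level = 0.9, k = 4L,
                                min_obs = 25L, hidden = c(24L),
                                control = list(), seed = NULL) {
  regime <- match.arg(regime)
  x <- feature_matrix(table)
  y <- table$pain_label
  fit_one <- function(rows, seed_offset) {
    pinet(x[rows, , drop = FALSE], y[rows], method = method, level = level,
          hidden = hidden, control = control,
          seed = if (is.null(seed)) NULL else seed + seed_offset)
  }
  obj <- list(regime = regime, method = method, level = level)
  if (regime == "generalized") {
    obj$models <- list(all = fit_one(seq_len(nrow(table)), 0L))
  } else if (regime == "personalized") {
    subs <- levels(factor(table$subject_id))
    models <- list()
    for (i in seq_along(subs)) {
      rows <- which(table$subject_id == subs[i])
      if (length(rows) < min_obs) {
        warning("subject ", subs[i], " has ", length(rows),
                " rows (< ", min_obs, "); skipped")
        next
      }
      models[[subs[i]]] <- fit_one(rows, i - 1L)
    }
    if (length(models) == 0L) stop("no subject reached min_obs rows")
    obj$models <- models
  } else {
    ## clustering precedes any split: global scaler on all rows
    scaler <- fit_minmax(x)
    tab_norm <- table
    tab_norm[, feature_columns(table)] <- predict(scaler, x)
    vec <- subject_vectors(tab_norm)
    cl <- kmeans_subjects(vec, k = k, seed = seed)
    subject_cluster <- cl$cluster
    models <- list()
    for (c_ in seq_len(k)) {
      members <- names(subject_cluster)[subject_cluster == c_]
      rows <- which(table$subject_id %in% members)
      models[[paste0("cluster", c_)]] <- fit_one(rows, c_ - 1L)
    }
    obj$models <- models
    obj$clusters <- cl
    obj$cluster_scaler <- scaler
  }
  structure(obj, class = "cohort_models")
}

#' @export
print.cohort_models <- function(x, ...) {
  cat("Cohort model set:", x$regime, "regime,", length(x$models),
      "model(s),", x$method, "method at nominal level", format(x$level), "\n")
  invisible(x)
}

#' Predict intervals from a cohort model set
#'
#' Routes each observation to the regime's model: the single generalized
#' model, the subject's own model (personalized; unseen subjects error),
#' or the model of the nearest cluster, found from the subject's summary
#' vector (hybrid).
#'
#' @param object A [build_cohort_models()] fit.
#' @param newdata Cohort table of observations to predict.
#' @param ... Unused.
#' @return A `data.frame` with `lower`, `upper` in the row order of
#'   `newdata`.
#' @export
predict.cohort_models <- function(object, newdata, ...) {
  x <- feature_matrix(newdata)
  out <- data.frame(lower = rep(NA_real_, nrow(newdata)),
                    upper = rep(NA_real_, nrow(newdata)))
  if (object$regime == "generalized") {
    return(predict(object$models$all, x))
  }
  if (object$regime == "personalized") {
    for (s in unique(as.character(newdata$subject_id))) {
      if (is.null(object$models[[s]]))
        stop("no personalized model for subject ", s)
      rows <- which(newdata$subject_id == s)
      out[rows, ] <- predict(object$models[[s]], x[rows, , drop = FALSE])
    }
    return(out)
  }
  ## hybrid: subjects seen at clustering time keep their fitted cluster;
  ## new subjects are routed via their normalized summary vectors
  subs <- unique(as.character(newdata$subject_id))
  known <- intersect(subs, names(object$clusters$cluster))
  cl_of <- object$clusters$cluster[known]
  new_subs <- setdiff(subs, known)
  if (length(new_subs) > 0) {
    keep <- newdata$subject_id %in% new_subs
    tab_norm <- newdata[keep, , drop = FALSE]
    tab_norm$subject_id <- factor(as.character(tab_norm$subject_id))
    tab_norm[, feature_columns(newdata)] <-
      predict(object$cluster_scaler, x[keep, , drop = FALSE])
    vec <- subject_vectors(tab_norm)
    cl_new <- assign_subject(vec, object$clusters)
    names(cl_new) <- rownames(vec)
    cl_of <- c(cl_of, cl_new)
  }
  for (s in names(cl_of)) {
    rows <- which(as.character(newdata$subject_id) == s)
    mod <- object$models[[paste0("cluster", cl_of[[s]])]]
    out[rows, ] <- predict(mod, x[rows, , drop = FALSE])
  }
  out
}
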