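test_that("k-means recovers planted clusters exactly", {
  pv <- planted_vectors(n_per = 6, k = 4, seed = 1)
  cm <- kmeans_subjects(pv$vectors, k = 4, seed = 2)
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(cm$cluster, pv$truth), 1)
})

test_that("Lloyd inertia is non-increasing and matches stats::kmeans", {
  pv <- planted_vectors(n_per = 5, k = 3, dim = 20, sep = 2, sd = 1, seed = 3)
  cm <- kmeans_subjects(pv$vectors, k = 3, seed = 4)
  expect_true(all(diff(cm$inertia_trace) <= 1e-8))
  ## independent implementation reaches the same objective
  ref <- stats::kmeans(pv$vectors, centers = 3, nstart = 20,
                       algorithm = "Lloyd", iter.max = 100)
  expect_equal(cm$inertia, ref$tot.withinss, tolerance = 1e-6)
})

test_that("k = 1 collapses to the global mean", {
  pv <- planted_vectors(n_per = 4, k = 2, dim = 10, seed = 5)
  cm <- kmeans_subjects(pv$vectors, k = 1, seed = 6)
  expect_equal(as.numeric(cm$centroids), colMeans(pv$vectors))
  expect_true(all(cm$cluster == 1))
})

test_that("converged partitions are locally optimal on small instances", {
  set.seed(7)
  v <- matrix(rnorm(12 * 4), 12, 4)
  rownames(v) <- sprintf("S%02d", 1:12)
  cm <- kmeans_subjects(v, k = 3, seed = 8)
  inertia_of <- function(assign) {
    sum(sapply(unique(assign), function(c_) {
      pts <- v[assign == c_, , drop = FALSE]
      sum(sweep(pts, 2, colMeans(pts))^2)
    }))
  }
  base <- inertia_of(cm$cluster)
  expect_equal(base, cm$inertia, tolerance = 1e-8)
  ## no single-point reassignment lowers the objective
  for (i in 1:12) for (c_ in 1:3) {
    if (cm$cluster[i] == c_) next
    alt <- cm$cluster; alt[i] <- c_
    if (length(unique(alt)) < 3) next
    expect_gte(inertia_of(alt), base - 1e-8)
  }
})

test_that("subject assignment uses nearest centroid with low-index ties", {
  pv <- planted_vectors(n_per = 4, k = 3, dim = 6, seed = 9)
  cm <- kmeans_subjects(pv$vectors, k = 3, seed = 10)
  ## a centroid maps to its own cluster
  expect_equal(assign_subject(cm$centroids[2, ], cm), 2L)
  ## training subjects keep their fitted assignments
  expect_equal(unname(assign_subject(pv$vectors, cm)), unname(cm$cluster))
  ## exact midpoint between two centroids goes to the lower index
  mid <- (cm$centroids[1, ] + cm$centroids[3, ]) / 2
  d2 <- rowSums(sweep(cm$centroids, 2, mid)^2)
  if (abs(d2[1] - d2[3]) < 1e-12 && all(d2[2] > d2[c(1, 3)]))
    expect_equal(assign_subject(mid, cm), 1L)
  expect_error(assign_subject(rnorm(5), cm), "dimension")
})

test_that("pairwise distance summaries have the right counts and symmetries", {
  pv <- planted_vectors(n_per = 5, k = 2, dim = 8, seed = 11)
  st <- pairwise_distance_stats(pv$vectors, pv$truth)
  expect_equal(st$n_pairs, rep(choose(5, 2), 2))
  ## translation invariance
  st2 <- pairwise_distance_stats(pv$vectors + 7, pv$truth)
  expect_equal(st$mean, st2$mean, tolerance = 1e-10)
  ## identical subjects sit at distance zero
  v0 <- rbind(a = rep(1, 4), b = rep(1, 4))
  st0 <- pairwise_distance_stats(v0, c(1, 1))
  expect_equal(st0$mean, 0)
  expect_warning(pairwise_distance_stats(pv$vectors[1:3, ], c(1, 1, 2)),
                 "fewer than 2")
})

test_that("regimes build the expected number of models", {
  tab <- tiny_cohort(seed = 12, n_subjects = 8, obs = 4)
  ctl <- list(epochs = 5)
  g <- build_cohort_models(tab, "generalized", control = ctl, seed = 1)
  expect_length(g$models, 1)
  h <- build_cohort_models(tab, "hybrid", k = 4, control = ctl, seed = 1)
  expect_length(h$models, 4)
  expect_s3_class(h$clusters, "subject_clusters")
  p <- build_cohort_models(tab, "personalized", min_obs = 10,
                           control = ctl, seed = 1)
  expect_length(p$models, 8)
  ## a subject below the row threshold is skipped with a warning
  short <- tab[-(which(tab$subject_id == "S001")[1:10]), ]
  expect_warning(
    ps <- build_cohort_models(short, "personalized", min_obs = 15,
                              control = ctl, seed = 1),
    "skipped")
  expect_length(ps$models, 7)
})

test_that("hybrid with one cluster reduces exactly to the generalized regime", {
  tab <- tiny_cohort(seed = 13, n_subjects = 6, obs = 3)
  ctl <- list(epochs = 10)
  g <- build_cohort_models(tab, "generalized", control = ctl, seed = 5)
  h <- build_cohort_models(tab, "hybrid", k = 1, control = ctl, seed = 5)
  pg <- predict(g, tab)
  ph <- predict(h, tab)
  expect_equal(pg$lower, ph$lower)
  expect_equal(pg$upper, ph$upper)
})

test_that("per-cluster metrics aggregate to cohort metrics by weighting", {
  b <- random_batch(120, 14)
  groups <- rep(1:3, times = c(20, 40, 60))
  pooled <- pi_quality(b, 4, 0.9)
  per <- lapply(1:3, function(g) {
    idx <- groups == g
    q <- pi_quality(interval_batch(b$lower[idx], b$upper[idx], b$target[idx]),
                    4, 0.9)
    cbind(q, n = sum(idx))
  })
  per <- do.call(rbind, per)
  expect_equal(weighted.mean(per$picp, per$n), pooled$picp)
  expect_equal(weighted.mean(per$mpiw, per$n), pooled$mpiw)
  expect_equal(weighted.mean(per$nmpiw, per$n), pooled$nmpiw)
})
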