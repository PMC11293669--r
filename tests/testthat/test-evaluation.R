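narrow_space <- function() {
  sp <- search_space()
  sp$net$layers <- c(1L, 1L)
  sp$net$neurons <- c(4L, 8L)
  sp$net$activation <- "relu"
  sp
}

test_that("sampled configurations stay inside the published ranges", {
  d <- simulate_known_quantiles(120, "gaussian", level = 0.9, seed = 1)
  x <- matrix((d$x - min(d$x)) / diff(range(d$x)))
  res <- hyperparameter_search(x, d$y, "soft", budget = 5, level = 0.9,
                               epochs = 5, space = narrow_space(), seed = 2)
  tr <- res$trace
  sp <- search_space()$gd
  expect_true(all(tr$lr >= sp$lr[1] & tr$lr <= sp$lr[2]))
  expect_true(all(tr$lam >= sp$lam[1] & tr$lam <= sp$lam[2]))
  expect_true(all(tr$eta >= sp$eta[1] & tr$eta <= sp$eta[2]))
  expect_true(all(tr$s >= sp$s[1] & tr$s <= sp$s[2]))
  expect_true(all(tr$mu == 0.9))
  expect_equal(nrow(tr), 5)
})

test_that("a budget of one returns the single sampled configuration", {
  d <- simulate_known_quantiles(80, "gaussian", level = 0.9, seed = 3)
  x <- matrix(d$x)
  res <- hyperparameter_search(x, d$y, "soft", budget = 1, level = 0.9,
                               epochs = 3, space = narrow_space(), seed = 4)
  expect_equal(res$best_index, 1L)
  expect_true(is.list(res$best))
  expect_error(hyperparameter_search(x, d$y, budget = 0), "budget")
})

test_that("GA search records its parameters within range", {
  tab <- tiny_cohort(seed = 5, n_subjects = 4, obs = 2)
  x <- predict(fit_minmax(tab), tab)
  res <- hyperparameter_search(x, tab$pain_label, "lube", budget = 3,
                               level = 0.85, n_generations = 5,
                               space = narrow_space(), seed = 6)
  sp <- search_space()$ga
  tr <- res$trace
  expect_true(all(tr$n_solutions >= sp$n_solutions[1] &
                    tr$n_solutions <= sp$n_solutions[2]))
  expect_true(all(tr$eta >= sp$eta[1] & tr$eta <= sp$eta[2]))
})

test_that("evaluate_method reports NMPIW = MPIW / R and mean-aggregated folds", {
  tab <- tiny_cohort(seed = 7, n_subjects = 6, obs = 4)
  res <- evaluate_method(tab, "soft", "generalized", levels = c(0.5, 0.85),
                         n_folds = 2, hidden = 6,
                         control = list(epochs = 15), seed = 8)
  expect_equal(res$folds$nmpiw, res$folds$mpiw / 4, tolerance = 1e-12)
  for (lv in c(0.5, 0.85)) {
    sub <- res$folds[res$folds$nominal == lv, ]
    expect_equal(res$summary$picp[res$summary$nominal == lv], mean(sub$picp))
    expect_equal(res$summary$mpiw[res$summary$nominal == lv], mean(sub$mpiw))
  }
  ## per-level bound table has one row per level and nominal
  expect_equal(nrow(res$level_bounds), 2 * 5)
  expect_error(evaluate_method(tab, "magic"), "unknown method")
})

test_that("bootstrap width is non-decreasing in the nominal level", {
  tab <- tiny_cohort(seed = 9, n_subjects = 6, obs = 4)
  res <- evaluate_method(tab, "bootstrap", "generalized",
                         levels = c(0.5, 0.95), n_folds = 2,
                         control = list(B = 4, size = 3, maxit = 60),
                         seed = 10)
  expect_lt(res$summary$mpiw[res$summary$nominal == 0.5],
            res$summary$mpiw[res$summary$nominal == 0.95])
})

test_that("report writes deterministic CSV and JSON outputs", {
  tab <- tiny_cohort(seed = 11, n_subjects = 6, obs = 3)
  res <- evaluate_method(tab, "soft", "generalized", levels = 0.85,
                         n_folds = 2, hidden = 4,
                         control = list(epochs = 5), seed = 12)
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  p1 <- report(res, d1, figures = FALSE)
  p2 <- report(res, d2, figures = FALSE)
  for (i in seq_along(p1))
    expect_identical(readLines(p1[i]), readLines(p2[i]))
  summ <- read.csv(file.path(d1, "summary.csv"))
  expect_named(summ, c("regime", "method", "nominal", "picp", "mpiw",
                       "nmpiw", "crossing_fraction"))
  ## figures are written when requested
  p3 <- report(res, file.path(tempdir(), "rep3"), figures = TRUE)
  expect_true(file.exists(p3[length(p3)]))
})
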