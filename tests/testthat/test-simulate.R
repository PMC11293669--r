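test_that("cohort generation is seed-deterministic and has the declared shape", {
  cfg <- cohort_config(n_subjects = 6, obs_per_subject_level = 3, seed = 42)
  tab1 <- simulate_cohort(cfg)
  tab2 <- simulate_cohort(cfg)
  expect_identical(tab1, tab2)
  expect_equal(nrow(tab1), 6 * 5 * 3)
  expect_equal(length(grep("^f", names(tab1))), 22)
  expect_true(all(tab1$pain_label %in% 0:4))
  expect_equal(nlevels(tab1$cluster_truth), 4)
  ## different seeds give different draws
  tab3 <- simulate_cohort(cohort_config(n_subjects = 6,
                                        obs_per_subject_level = 3, seed = 43))
  expect_false(identical(tab1$f01, tab3$f01))
})

test_that("cleaning drops exactly the rows with missing cells, near the study scale", {
  tab <- simulate_cohort(cohort_config(seed = 7))  # 87 x 5 x 20, 1% missing
  expect_equal(nrow(tab), 8700)
  clean <- clean_cohort(tab)
  expect_false(anyNA(clean[, grep("^f", names(clean))]))
  ## per-row missingness at 1% leaves about 8613 of 8700 rows
  expect_gt(nrow(clean), 8612 - 40)
  expect_lt(nrow(clean), 8612 + 40)
})

test_that("degenerate generator collapses within cluster and level", {
  tab <- simulate_cohort(cohort_config(
    n_subjects = 8, obs_per_subject_level = 5, effect_size = 0,
    subject_sd = 0, noise_sd_base = 1e-12, missing_rate = 0, seed = 3))
  f <- tab[, grep("^f", names(tab))]
  for (cl in levels(tab$cluster_truth)) {
    rows <- tab$cluster_truth == cl
    expect_lt(max(apply(f[rows, ], 2, sd)), 1e-9)
  }
})

test_that("generator validates its configuration", {
  expect_error(cohort_config(n_subjects = 0), "positive")
  expect_error(cohort_config(noise_sd_base = 0), "noise_sd_base")
  expect_error(cohort_config(missing_rate = 1.2), "missing_rate")
  expect_error(cohort_config(n_clusters = 10, n_subjects = 5), "n_clusters")
})

test_that("per-level noise follows the heteroscedastic schedule", {
  base <- 0.2; het <- 0.5
  tab <- simulate_cohort(cohort_config(
    n_subjects = 4, obs_per_subject_level = 300, n_features = 4,
    effect_size = 0, subject_sd = 0, noise_sd_base = base,
    heteroscedasticity = het, missing_rate = 0, seed = 11))
  f <- as.matrix(tab[, grep("^f", names(tab))])
  for (l in 0:4) {
    rows <- tab$pain_label == l
    ## residual sd around the subject/cluster mean, pooled over features
    res <- sapply(levels(tab$subject_id), function(s) {
      sub <- f[rows & tab$subject_id == s, , drop = FALSE]
      apply(sub, 2, sd)
    })
    expect_equal(mean(res), base * (1 + het * l), tolerance = 0.05)
  }
})

test_that("known-quantile oracle has the closed-form width and coverage", {
  d <- simulate_known_quantiles(200, "gaussian", sd = 1, level = 0.95, seed = 5)
  expect_equal(unique(round(d$oracle_upper - d$oracle_lower, 10)),
               round(2 * qnorm(0.975), 10))
  ## Monte-Carlo coverage at n = 10000 stays inside the binomial band
  big <- simulate_known_quantiles(10000, "gaussian", level = 0.95, seed = 6)
  cover <- mean(big$y >= big$oracle_lower & big$y <= big$oracle_upper)
  expect_gt(cover, 0.94)
  expect_lt(cover, 0.96)
  ## vanishing noise collapses the oracle width
  d0 <- simulate_known_quantiles(50, "gaussian", sd = 1e-12, seed = 7)
  expect_lt(max(d0$oracle_upper - d0$oracle_lower), 1e-10)
  expect_error(simulate_known_quantiles(5, "gaussian"), "n must be")
  expect_error(simulate_known_quantiles(100, "cauchy"), "arg")
})

test_that("heteroscedastic oracle widens with x and still covers", {
  d <- simulate_known_quantiles(8000, "heteroscedastic", sd = 1,
                                level = 0.9, seed = 8)
  w <- d$oracle_upper - d$oracle_lower
  expect_gt(cor(w, d$x), 0.99)     # width grows linearly in x
  cover <- mean(d$y >= d$oracle_lower & d$y <= d$oracle_upper)
  expect_equal(cover, 0.9, tolerance = 0.015)
})

test_that("cohort CSV round trip preserves the table", {
  tab <- tiny_cohort(seed = 2, n_subjects = 4, obs = 2)
  f <- tempfile(fileext = ".csv")
  write_cohort_csv(tab, f)
  back <- read_cohort_csv(f)
  expect_equal(back$pain_label, tab$pain_label)
  expect_equal(as.character(back$subject_id), as.character(tab$subject_id))
  expect_equal(back$f07, tab$f07, tolerance = 1e-12)
})
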