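#' Configuration for a synthetic EDA-feature cohort
#'
#' Describes a cohort with the statistical structure the interval models
#' assume: per-subject feature vectors whose means shift with pain level,
#' subject-level random effects, latent subject clusters, and noise whose
#' scale grows with pain level. Defaults mirror the scale of an 87-subject
#' electrodermal-activity study with 22 features and five pain levels (0-4).
#'
#' @param n_subjects Number of subjects (default 87).
#' @param obs_per_subject_level Observations per subject per pain level.
#' @param n_features Number of features (default 22).
#' @param n_clusters Number of latent subject clusters (default 4).
#' @param effect_size Per-level shift of the feature means: feature j of a
#'   subject in cluster c shifts by `effect_size * level * w[c, j]`, where
#'   the loadings `w` are drawn once per cohort (see
#'   `cluster_response_sd`).
#' @param cluster_response_sd Spread of the per-cluster response loadings
#'   `w[c, j] ~ N(1, cluster_response_sd)`. At 0 every cluster expresses
#'   pain level through the features identically; above 0 the
#'   feature-to-pain mapping differs between latent clusters, the
#'   heterogeneity that motivates cluster-specific (hybrid) models.
#' @param subject_sd Standard deviation of the per-subject random effect
#'   added to every feature.
#' @param noise_sd_base Baseline observation noise sd (must be > 0).
#' @param heteroscedasticity Relative growth of the noise sd with pain
#'   level: sd at level `l` is `noise_sd_base * (1 + heteroscedasticity * l)`.
#' @param cluster_sd Spread of the cluster centroids in feature space.
#' @param missing_rate Probability that a row has one missing feature cell
#'   (removable by [clean_cohort()]).
#' @param label_jitter Scale of optional jitter added to the integer pain
#'   labels (0 disables; labels stay clamped to \[0, 4\]). Uniform jitter
#'   uses this as half-width, t jitter as the scale of the t variate.
#' @param label_noise Distribution of the label jitter: `"uniform"`, or
#'   `"t"` (Student t with `label_noise_df` degrees of freedom), the
#'   heavy-tailed choice emulating occasional large self-report errors in
#'   pain ratings.
#' @param label_noise_df Degrees of freedom of the t jitter.
#' @param seed Optional integer seed.
#'
#' @return An object of class `cohort_config`.
#' @seealso [simulate_cohort()]
#' @export
cohort_config <- function(n_subjects = 87L,
                          obs_per_subject_level = 20L,
                          n_features = 22L,
                          n_clusters = 4L,
                          effect_size = 0.25,
                          cluster_response_sd = 0.5,
                          subject_sd = 0.3,
                          noise_sd_base = 0.15,
                          heteroscedasticity = 0.15,
                          cluster_sd = 1,
                          missing_rate = 0.01,
                          label_jitter = 0,
                          label_noise = c("uniform", "t"),
                          label_noise_df = 3,
                          seed = NULL) {
  counts <- c(n_subjects = n_subjects,
              obs_per_subject_level = obs_per_subject_level,
              n_features = n_features, n_clusters = n_clusters)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("counts must be positive integers: ",
         paste(names(counts)[counts < 1 | counts != round(counts)],
               collapse = ", "))
  if (n_clusters > n_subjects)
    stop("n_clusters must not exceed n_subjects")
  if (noise_sd_base <= 0) stop("noise_sd_base must be > 0")
  if (subject_sd < 0) stop("subject_sd must be >= 0")
  if (heteroscedasticity < 0) stop("heteroscedasticity must be >= 0")
  if (cluster_sd < 0) stop("cluster_sd must be >= 0")
  if (cluster_response_sd < 0) stop("cluster_response_sd must be >= 0")
  if (missing_rate < 0 || missing_rate > 1)
    stop("missing_rate must be in [0, 1]")
  if (label_jitter < 0) stop("label_jitter must be >= 0")
  label_noise <- match.arg(label_noise)
  if (label_noise_df <= 2) stop("label_noise_df must be > 2 (finite variance)")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_levels = 5L,
                 obs_per_subject_level = as.integer(obs_per_subject_level),
                 n_features = as.integer(n_features),
                 n_clusters = as.integer(n_clusters),
                 effect_size = effect_size,
                 cluster_response_sd = cluster_response_sd,
                 subject_sd = subject_sd,
                 noise_sd_base = noise_sd_base,
                 heteroscedasticity = heteroscedasticity,
                 cluster_sd = cluster_sd,
                 missing_rate = missing_rate,
                 label_jitter = label_jitter,
                 label_noise = label_noise,
                 label_noise_df = label_noise_df,
                 seed = seed),
            class = "cohort_config")
}

#' Simulate a synthetic feature-table cohort
#'
#' Draws a cohort according to a [cohort_config()]: each observation is
#' cluster centroid + subject random effect + level-proportional shift +
#' Gaussian noise whose sd follows the heteroscedastic schedule
#' `noise_sd_base * (1 + heteroscedasticity * level)`. A fraction
#' `missing_rate` of rows receives one missing feature cell, to be removed
#' by [clean_cohort()]. Deterministic given the seed.
#'
#' @param config A `cohort_config`.
#' @return A `data.frame` with columns `subject_id` (factor), `pain_label`
#'   (numeric in \[0, 4\]), `cluster_truth` (factor; generator ground truth),
#'   and features `f01..fNN`.
#' @examples
#' tab <- simulate_cohort(cohort_config(n_subjects = 8,
#'                                      obs_per_subject_level = 3,
#'                                      seed = 1))
#' nrow(tab)  # 8 * 5 * 3
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  seed_rng(config$seed)
  p <- config$n_features
  n_sub <- config$n_subjects
  m <- config$obs_per_subject_level
  levels_ <- 0:(config$n_levels - 1L)

  centroids <- matrix(stats::rnorm(config$n_clusters * p, sd = config$cluster_sd),
                      nrow = config$n_clusters)
  ## per-cluster response loadings of the level shift
  loadings <- matrix(1 + stats::rnorm(config$n_clusters * p,
                                      sd = config$cluster_response_sd),
                     nrow = config$n_clusters)
  cluster_of <- sample(rep_len(seq_len(config$n_clusters), n_sub))
  subject_eff <- matrix(stats::rnorm(n_sub * p, sd = config$subject_sd),
                        nrow = n_sub)

  n_rows <- n_sub * config$n_levels * m
  subject_idx <- rep(seq_len(n_sub), each = config$n_levels * m)
  level <- rep(rep(levels_, each = m), times = n_sub)

  mu <- centroids[cluster_of[subject_idx], , drop = FALSE] +
    subject_eff[subject_idx, , drop = FALSE] +
    config$effect_size * level * loadings[cluster_of[subject_idx], , drop = FALSE]
  noise_sd <- config$noise_sd_base * (1 + config$heteroscedasticity * level)
  x <- mu + matrix(stats::rnorm(n_rows * p), nrow = n_rows) * noise_sd

  label <- as.numeric(level)
  if (config$label_jitter > 0) {
    jit <- switch(config$label_noise,
                  uniform = stats::runif(n_rows, -config$label_jitter,
                                         config$label_jitter),
                  t = config$label_jitter * stats::rt(n_rows,
                                                      config$label_noise_df))
    label <- pmin(pmax(label + jit, 0), 4)
  }

  if (config$missing_rate > 0) {
    hit <- stats::runif(n_rows) < config$missing_rate
    if (any(hit)) {
      cells <- sample.int(p, sum(hit), replace = TRUE)
      x[cbind(which(hit), cells)] <- NA_real_
    }
  }

  ids <- sprintf("S%03d", seq_len(n_sub))
  out <- data.frame(subject_id = factor(ids[subject_idx], levels = ids),
                    pain_label = label,
                    cluster_truth = factor(cluster_of[subject_idx]),
                    stringsAsFactors = FALSE)
  colnames(x) <- sprintf("f%02d", seq_len(p))
  cbind(out, as.data.frame(x))
}

#' Remove incomplete observations from a cohort table
#'
#' Drops every row with a missing feature value (the cleaning step applied
#' before modelling) and validates the cleaned table: all features finite,
#' labels within \[0, 4\].
#'
#' @param table A cohort `data.frame` as produced by [simulate_cohort()].
#' @return The cleaned table.
#' @export
clean_cohort <- function(table) {
  x <- feature_matrix(table)
  keep <- stats::complete.cases(x)
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (!all(is.finite(feature_matrix(out))))
    stop("non-finite feature values remain after cleaning")
  if (any(out$pain_label < 0 | out$pain_label > 4))
    stop("pain_label outside [0, 4]")
  out
}

#' Simulate a regression problem with known conditional quantiles
#'
#' A one-dimensional benchmark for coverage validation: `y = x + eps` with a
#' fully known noise law, so the true conditional alpha/2 and 1 - alpha/2
#' quantiles (the oracle interval bounds) are available in closed form.
#' Under `"gaussian"` noise the oracle width is constant,
#' `2 * qnorm(1 - (1 - level) / 2) * sd`; under `"heteroscedastic"` noise the
#' sd grows linearly across the x-range from `0.5 * sd` to `1.5 * sd`.
#'
#' @param n Number of observations (>= 10).
#' @param noise `"gaussian"` or `"heteroscedastic"`.
#' @param sd Baseline noise standard deviation.
#' @param level Nominal coverage 1 - alpha of the oracle interval.
#' @param xlim Range of the uniform design points.
#' @param seed Optional integer seed.
#' @return A `data.frame` with columns `x`, `y`, `oracle_lower`,
#'   `oracle_upper` and attribute `level`.
#' @examples
#' d <- simulate_known_quantiles(100, seed = 1)
#' mean(d$y >= d$oracle_lower & d$y <= d$oracle_upper)
#' @export
simulate_known_quantiles <- function(n, noise = c("gaussian", "heteroscedastic"),
                                     sd = 1, level = 0.95,
                                     xlim = c(-2, 2), seed = NULL) {
  noise <- match.arg(noise)
  if (n < 10) stop("n must be >= 10")
  if (sd < 0) stop("sd must be >= 0")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  seed_rng(seed)
  x <- stats::runif(n, xlim[1], xlim[2])
  mu <- x
  sd_x <- switch(noise,
                 gaussian = rep(sd, n),
                 heteroscedastic = sd * (0.5 + (x - xlim[1]) / diff(xlim)))
  y <- mu + stats::rnorm(n) * sd_x
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- data.frame(x = x, y = y,
                    oracle_lower = mu - z * sd_x,
                    oracle_upper = mu + z * sd_x)
  attr(out, "level") <- level
  out
}

#' Write or read a cohort feature table as CSV
#'
#' Plain-text round trip for cohort tables (header
#' `subject_id, pain_label, f01..`); `cluster_truth` is preserved when
#' present.
#'
#' @param table A cohort `data.frame`.
#' @param file Path to a CSV file.
#' @return `read_cohort_csv` returns the table; `write_cohort_csv` returns
#'   `file` invisibly.
#' @export
write_cohort_csv <- function(table, file) {
  utils::write.csv(table, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(file) {
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  tab$subject_id <- factor(tab$subject_id)
  if ("cluster_truth" %in% names(tab))
    tab$cluster_truth <- factor(tab$cluster_truth)
  tab
}
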