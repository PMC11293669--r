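## small cohort used across tests
tiny_cohort <- function(seed = 1, n_subjects = 8L, obs = 4L, ...) {
  clean_cohort(simulate_cohort(cohort_config(
    n_subjects = n_subjects, obs_per_subject_level = obs,
    n_clusters = min(4L, n_subjects), missing_rate = 0, seed = seed, ...)))
}

## the frozen study conditions for cohort-level model comparisons:
## 4 separated latent clusters with heterogeneous level responses,
## modest sensor noise and heavy-tailed self-report label noise
study_cohort <- function(seed, n_subjects = 24L, obs = 20L) {
  clean_cohort(simulate_cohort(cohort_config(
    n_subjects = n_subjects, obs_per_subject_level = obs,
    missing_rate = 0, noise_sd_base = 0.15,
    label_jitter = 0.5, label_noise = "t", seed = seed)))
}

## random interval batch with margins bounded away from the bounds
random_batch <- function(n, seed, min_margin = 0) {
  set.seed(seed)
  target <- runif(n, 0, 4)
  half <- runif(n, min_margin + 0.05, 2)
  centre <- target + runif(n, -1, 1) * (half - min_margin)
  interval_batch(centre - half, centre + half, target)
}

## well-separated planted subject vectors for cluster-recovery tests
planted_vectors <- function(n_per = 6L, k = 4L, dim = 110L, sep = 8,
                            sd = 0.3, seed = 1) {
  set.seed(seed)
  centres <- matrix(rnorm(k * dim), k) * sep
  truth <- rep(seq_len(k), each = n_per)
  v <- centres[truth, ] + matrix(rnorm(n_per * k * dim, sd = sd), n_per * k)
  rownames(v) <- sprintf("S%03d", seq_len(nrow(v)))
  list(vectors = v, truth = truth)
}

## reference soft-loss value computed with plain arithmetic, independent
## of the package implementation
loss_soft_reference <- function(lower, upper, target, lam, eta, alpha, s) {
  k <- as.numeric(lower <= target & target <= upper)
  w <- upper - lower
  mpiw_s <- if (sum(k) == 0) mean(w) else sum(k * w) / sum(k)
  p <- mean(plogis(s * (target - lower)) * plogis(s * (upper - target)))
  mpiw_s + lam * (eta / (alpha * (1 - alpha))) * max(0, (1 - alpha) - p)^2
}
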