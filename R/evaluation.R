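#' Published hyperparameter search spaces
#'
#' The search ranges for the network architecture, the GA/LUBE-loss
#' parameters and the GD/soft-loss parameters, exactly as published:
#' 1-4 hidden layers of 10-150 neurons with relu/tanh/linear activation;
#' GA with 10-20 solutions, 5-10 mating parents, 10-20% mutated genes,
#' LUBE eta in \[25, 100\] and mu in \[0.5, 0.95\]; GD with learning rate
#' \[0.001, 0.1\], decay \[1e-6, 1e-4\], soft-loss lambda \[5, 30\],
#' eta \[35, 240\], mu \[0.5, 0.95\] and softening factor s \[10, 220\].
#'
#' @return A nested list of ranges (`net`, `ga`, `gd`).
#' @export
search_space <- function() {
  list(net = list(layers = c(1L, 4L), neurons = c(10L, 150L),
                  activation = c("relu", "tanh", "linear")),
       ga = list(n_solutions = c(10L, 20L), n_parents_mating = c(5L, 10L),
                 mutation_percent_genes = c(10, 20),
                 eta = c(25, 100), mu = c(0.5, 0.95)),
       gd = list(lr = c(0.001, 0.1), decay = c(1e-6, 1e-4),
                 lam = c(5, 30), eta = c(35, 240), mu = c(0.5, 0.95),
                 s = c(10, 220)))
}

runif1 <- function(rng) stats::runif(1, rng[1], rng[2])
sampint <- function(rng) sample(seq(rng[1], rng[2]), 1L)

## one random configuration from the published spaces
sample_config <- function(space = search_space(),
                          method = c("soft", "lube"), mu = NULL) {
  method <- match.arg(method)
  n_layers <- sampint(space$net$layers)
  cfg <- list(hidden = vapply(seq_len(n_layers), function(i)
                sampint(space$net$neurons), integer(1)),
              activation = sample(space$net$activation, 1L))
  if (method == "soft") {
    cfg <- c(cfg, list(lr = runif1(space$gd$lr),
                       decay = runif1(space$gd$decay),
                       lam = runif1(space$gd$lam),
                       eta = runif1(space$gd$eta),
                       mu = mu %||% runif1(space$gd$mu),
                       s = runif1(space$gd$s)))
  } else {
    cfg <- c(cfg, list(n_solutions = sampint(space$ga$n_solutions),
                       n_parents_mating = sampint(space$ga$n_parents_mating),
                       mutation_percent_genes = runif1(space$ga$mutation_percent_genes),
                       eta = runif1(space$ga$eta),
                       mu = mu %||% runif1(space$ga$mu)))
  }
  cfg
}

#' Random hyperparameter search over the published spaces
#'
#' Samples `budget` configurations uniformly from [search_space()], trains
#' each on a train split and scores it by the evaluation-mode loss on a
#' held-out validation split at the requested nominal level. The full
#' trace (configuration, validation loss, soft/hard coverage and width)
#' supports width-versus-coverage sensitivity plots.
#'
#' @param x,y Normalized features and targets.
#' @param method `"soft"` or `"lube"`.
#' @param budget Number of sampled configurations (>= 1).
#' @param level Nominal coverage; fixes mu = level in every sampled
#'   configuration (set `NULL` to sample mu from its range too).
#' @param val_frac Fraction of rows held out for validation.
#' @param epochs,n_generations Training budget per configuration.
#' @param space Search space (defaults to [search_space()]); narrow it to
#'   run controlled sweeps of a single parameter.
#' @param seed Optional integer seed.
#' @return A list: `best` (configuration with lowest validation loss) and
#'   `trace` (one row per configuration with its parameters and
#'   validation metrics).
#' @export
hyperparameter_search <- function(x, y, method = c("soft", "lube"),
                                  budget = 20L, level = 0.9,
                                  val_frac = 0.25, epochs = 40L,
                                  n_generations = 40L,
                                  space = search_space(), seed = NULL) {
  method <- match.arg(method)
  if (budget < 1) stop("budget must be >= 1")
  x <- as.matrix(x)
  n <- nrow(x)
  seed_rng(seed)
  val <- sample.int(n, max(1L, round(val_frac * n)))
  train <- setdiff(seq_len(n), val)
  rows <- vector("list", budget)
  fits <- vector("list", budget)
  for (i in seq_len(budget)) {
    cfg <- sample_config(space, method, mu = level)
    cfg_seed <- sample.int(.Machine$integer.max, 1L)
    if (method == "soft") {
      fit <- train_soft_gd(x[train, , drop = FALSE], y[train],
                           hidden = cfg$hidden, activation = cfg$activation,
                           lam = cfg$lam, eta = cfg$eta, alpha = 1 - cfg$mu,
                           s = cfg$s, lr = cfg$lr, decay = cfg$decay,
                           epochs = epochs, seed = cfg_seed)
      vb <- predict_bounds(fit$net, x[val, , drop = FALSE], y[val])
      comp <- loss_soft_components(vb, cfg$lam, cfg$eta, 1 - cfg$mu, cfg$s)
      rows[[i]] <- data.frame(config = i, layers = length(cfg$hidden),
                              neurons = mean(cfg$hidden),
                              activation = cfg$activation,
                              lr = cfg$lr, decay = cfg$decay, lam = cfg$lam,
                              eta = cfg$eta, mu = cfg$mu, s = cfg$s,
                              val_loss = comp$loss, picp_s = comp$picp_s,
                              mpiw_s = comp$mpiw_s, picp = picp(vb),
                              mpiw = mpiw(vb))
    } else {
      fit <- train_lube_ga(x[train, , drop = FALSE], y[train],
                           hidden = cfg$hidden, activation = cfg$activation,
                           eta = cfg$eta, mu = cfg$mu,
                           n_solutions = cfg$n_solutions,
                           n_parents_mating = cfg$n_parents_mating,
                           mutation_percent_genes = cfg$mutation_percent_genes,
                           n_generations = n_generations, seed = cfg_seed)
      vb <- predict_bounds(fit$net, x[val, , drop = FALSE], y[val])
      vloss <- loss_lube(vb, max(y) - min(y), cfg$eta, cfg$mu,
                         training = FALSE)
      rows[[i]] <- data.frame(config = i, layers = length(cfg$hidden),
                              neurons = mean(cfg$hidden),
                              activation = cfg$activation,
                              n_solutions = cfg$n_solutions,
                              n_parents_mating = cfg$n_parents_mating,
                              mutation_percent_genes = cfg$mutation_percent_genes,
                              eta = cfg$eta, mu = cfg$mu,
                              val_loss = vloss, picp = picp(vb),
                              mpiw = mpiw(vb))
    }
    fits[[i]] <- cfg
  }
  trace <- do.call(rbind, rows)
  best_i <- which.min(trace$val_loss)
  list(best = fits[[best_i]], best_index = best_i, trace = trace)
}

#' Per-pain-level mean interval bounds
#'
#' Groups observations by rounding the label to the nearest integer level
#' and reports the mean lower and upper bound per level.
#'
#' @param lower,upper Bound vectors.
#' @param labels Continuous pain labels.
#' @return A `data.frame` with columns `target`, `lower`, `upper`.
#' @export
level_bounds <- function(lower, upper, labels) {
  lev <- as.integer(round(labels))
  out <- lapply(sort(unique(lev)), function(l) {
    rows <- lev == l
    data.frame(target = l, lower = mean(lower[rows]),
               upper = mean(upper[rows]))
  })
  do.call(rbind, out)
}

#' Cross-validated evaluation of an interval method under a regime
#'
#' Runs k-fold cross-validation (level-stratified by default) of a method
#' (`"soft"`, `"lube"` or `"bootstrap"`) under a model-building regime at
#' one or more nominal coverage levels, computing achieved PICP, MPIW and
#' NMPIW (via the [pi_metrics][picp] functions) on the held-out fold and
#' the per-level mean bounds. Fold metrics are aggregated by their
#' unweighted mean.
#'
#' @param table A cleaned cohort table.
#' @param method Interval method.
#' @param regime Model-building regime.
#' @param levels Nominal coverage levels to evaluate.
#' @param n_folds Number of CV folds (default 10).
#' @param k Clusters for the hybrid regime.
#' @param hidden,control,min_obs Passed to [build_cohort_models()].
#' @param stratify_by Fold stratification (see [cv_folds()]); the default
#'   crosses subject and level so every subject keeps observations at
#'   every pain level in each training split, which the subject-vector
#'   construction of the hybrid regime requires.
#' @param seed Optional integer seed.
#' @return A list: `folds` (one row per nominal level and fold),
#'   `summary` (fold means per nominal level) and `level_bounds` (mean
#'   bounds per pain level and nominal level, pooled over folds).
#' @export
evaluate_method <- function(table, method = "soft",
                            regime = c("generalized", "personalized", "hybrid"),
                            levels = c(0.5, 0.75, 0.85, 0.95),
                            n_folds = 10L, k = 4L, hidden = c(24L),
                            control = list(), min_obs = 25L,
                            stratify_by = "subject_level", seed = NULL) {
  regime <- match.arg(regime)
  if (!method %in% c("soft", "lube", "bootstrap"))
    stop("unknown method: ", method)
  seed_rng(seed)
  fold <- cv_folds(table, n_folds, stratify_by,
                   seed = sample.int(.Machine$integer.max, 1L))
  target_range <- max(table$pain_label) - min(table$pain_label)
  rows <- list()
  lb_acc <- list()
  for (nominal in levels) {
    for (f in seq_len(n_folds)) {
      tr <- table[fold != f, , drop = FALSE]
      te <- table[fold == f, , drop = FALSE]
      fit_seed <- sample.int(.Machine$integer.max, 1L)
      models <- build_cohort_models(tr, regime, method = method,
                                    level = nominal, k = k,
                                    min_obs = min_obs, hidden = hidden,
                                    control = control, seed = fit_seed)
      if (regime == "personalized") {
        keep <- as.character(te$subject_id) %in% names(models$models)
        te <- te[keep, , drop = FALSE]
      }
      pred <- predict(models, te)
      batch <- interval_batch(pred$lower, pred$upper, te$pain_label)
      q <- pi_quality(batch, target_range, nominal)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(regime = regime, method = method, fold = f), q)
      lb <- level_bounds(pred$lower, pred$upper, te$pain_label)
      lb$nominal <- nominal
      lb$n <- as.integer(table(factor(as.integer(round(te$pain_label)),
                                      levels = lb$target)))
      lb_acc[[length(lb_acc) + 1L]] <- lb
    }
  }
  folds <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(levels, function(nv) {
    sub <- folds[folds$nominal == nv, ]
    data.frame(regime = regime, method = method, nominal = nv,
               picp = mean(sub$picp), mpiw = mean(sub$mpiw),
               nmpiw = mean(sub$nmpiw),
               crossing_fraction = mean(sub$crossing_fraction))
  }))
  lb_all <- do.call(rbind, lb_acc)
  lb_pooled <- do.call(rbind, lapply(split(lb_all,
                                           list(lb_all$nominal, lb_all$target)),
    function(g) data.frame(nominal = g$nominal[1], target = g$target[1],
                           lower = stats::weighted.mean(g$lower, g$n),
                           upper = stats::weighted.mean(g$upper, g$n))))
  lb_pooled <- lb_pooled[order(lb_pooled$nominal, lb_pooled$target), ]
  rownames(lb_pooled) <- NULL
  list(folds = folds, summary = summary, level_bounds = lb_pooled)
}

#' Write evaluation reports
#'
#' Writes the evaluation summary and per-level bound tables as CSV, the
#' full results as JSON, and (optionally) a coverage/width bar chart as
#' PDF. CSV and JSON outputs are byte-identical across re-runs on the same
#' rows.
#'
#' @param results A result list from [evaluate_method()], or a list of
#'   them (e.g. one per method or regime).
#' @param dir Output directory (created if needed).
#' @param figures Also write a summary bar chart (PDF).
#' @return Invisibly, the paths written.
#' @export
report <- function(results, dir, figures = TRUE) {
  if (!is.null(results$summary)) results <- list(results)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summary <- do.call(rbind, lapply(results, `[[`, "summary"))
  lb <- do.call(rbind, lapply(seq_along(results), function(i) {
    x <- results[[i]]$level_bounds
    cbind(data.frame(regime = results[[i]]$summary$regime[1],
                     method = results[[i]]$summary$method[1]), x)
  }))
  folds <- do.call(rbind, lapply(results, `[[`, "folds"))
  paths <- c(file.path(dir, "summary.csv"),
             file.path(dir, "level_bounds.csv"),
             file.path(dir, "results.json"))
  disp <- summary
  num <- vapply(disp, is.numeric, TRUE)
  disp[num] <- lapply(disp[num], round, 2)   # printed tables use 2 d.p.
  utils::write.csv(disp, paths[1], row.names = FALSE)
  utils::write.csv(lb, paths[2], row.names = FALSE)
  jsonlite::write_json(list(summary = summary, level_bounds = lb,
                            folds = folds),
                       paths[3], digits = NA, auto_unbox = TRUE)
  if (figures) {
    fig <- file.path(dir, "width_by_method.pdf")
    grDevices::pdf(fig, width = 7, height = 4)
    lab <- paste(summary$regime, summary$method, sprintf("%.0f%%",
                 100 * summary$nominal))
    graphics::barplot(summary$mpiw, names.arg = lab, las = 2,
                      cex.names = 0.6, ylab = "MPIW",
                      main = "Mean interval width by model and level")
    grDevices::dev.off()
    paths <- c(paths, fig)
  }
  invisible(paths)
}
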