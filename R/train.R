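#' Train an interval network on the soft loss by gradient descent
#'
#' Minibatch Adam on [loss_soft()]: per batch the forward pass produces
#' the bounds, [loss_soft_grad()] gives the gradient with respect to the
#' bounds, and backpropagation turns it into parameter gradients. The
#' effective learning rate decays as `lr / (1 + decay * step)`. Training
#' is deterministic given the seed; it stops at the epoch budget or when
#' the gradient norm falls below `grad_tol`.
#'
#' @param x Normalized feature matrix.
#' @param y Target vector.
#' @param hidden,activation Network architecture (see [interval_net()]).
#' @param lam,eta,alpha,s Soft-loss hyperparameters (see [loss_soft()]).
#' @param lr Learning rate (published search range 0.001-0.1).
#' @param decay Learning-rate decay (range 1e-6 to 1e-4).
#' @param weight_decay Decoupled L2 weight decay applied after each Adam
#'   update (`theta <- theta * (1 - lr_t * weight_decay)`). Regularizes
#'   the interval network when training sets are small (personalized
#'   models may see only a few dozen rows); 0 disables.
#' @param epochs Epoch budget.
#' @param batch_size Minibatch size.
#' @param grad_tol Stop when the full-gradient norm drops below this.
#' @param s_warmup Fraction of the step budget over which the softening
#'   factor is annealed geometrically from `min(5, s)` up to `s`. At large
#'   `s` the coverage sigmoids saturate for points far from the bounds and
#'   the coverage gradient vanishes before training can move the bounds;
#'   starting soft keeps the penalty informative everywhere. 0 disables.
#' @param clip Global gradient-norm clip: minibatch gradients with norm
#'   above this are rescaled. The coverage penalty is steep near the
#'   nominal level, and unclipped spikes can undo many width-shrinking
#'   steps through the optimizer's momentum.
#' @param seed Optional integer seed (controls init and shuffling).
#' @return A list with the trained `net`, a per-epoch `trace` data.frame
#'   (`epoch`, `loss`, `picp`, `mpiw`, `picp_s`, `mpiw_s`), and
#'   `guard_events`, the number of minibatches that captured no point.
#' @export
train_soft_gd <- function(x, y, hidden = c(32L), activation = "relu",
                          lam = 15, eta = 100, alpha = 0.1, s = 50,
                          lr = 0.03, decay = 1e-4, epochs = 500L,
                          batch_size = 128L, grad_tol = 1e-8, clip = 5,
                          weight_decay = 0, s_warmup = 0.5, seed = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(n == length(y), n >= 2)
  seed_rng(seed)
  net <- interval_net(ncol(x), hidden, activation, targets = y)
  theta <- net_flatten(net)
  m <- v <- numeric(length(theta))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  guard_events <- 0L
  trace <- vector("list", epochs)
  total_steps <- epochs * length(seq(1L, n, by = batch_size))
  s0 <- min(5, s)

  for (ep in seq_len(epochs)) {
    idx <- sample.int(n)
    starts <- seq(1L, n, by = batch_size)
    for (st in starts) {
      rows <- idx[st:min(st + batch_size - 1L, n)]
      if (length(rows) < 2L) next
      ## annealed softening factor for this step
      s_t <- if (s_warmup > 0)
        s0 * (s / s0)^min(1, step / (s_warmup * total_steps)) else s
      fwd <- net_forward(net, x[rows, , drop = FALSE], cache = TRUE)
      batch <- interval_batch(fwd$out[, 1], fwd$out[, 2], y[rows])
      comp <- loss_soft_components(batch, lam, eta, alpha, s_t)
      if (!is.finite(comp$loss))
        stop("non-finite soft loss at epoch ", ep,
             "; try a smaller learning rate or softening factor")
      if (comp$guard) guard_events <- guard_events + 1L
      g_bounds <- loss_soft_grad(batch, lam, eta, alpha, s_t)
      dout <- cbind(g_bounds$dlower, g_bounds$dupper)
      grads <- net_backward(net, fwd, dout)
      g <- unlist(lapply(grads, function(l) c(as.numeric(l$W), l$b)),
                  use.names = FALSE)
      gn <- sqrt(sum(g^2))
      if (is.finite(clip) && gn > clip) g <- g * (clip / gn)
      step <- step + 1L
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      m_hat <- m / (1 - beta1^step)
      v_hat <- v / (1 - beta2^step)
      lr_t <- lr / (1 + decay * step)
      theta <- theta - lr_t * m_hat / (sqrt(v_hat) + eps)
      if (weight_decay > 0) theta <- theta * (1 - lr_t * weight_decay)
      net <- net_unflatten(net, theta)
    }
    full <- predict_bounds(net, x, y)
    comp <- loss_soft_components(full, lam, eta, alpha, s)
    trace[[ep]] <- data.frame(epoch = ep, loss = comp$loss,
                              picp = picp(full), mpiw = mpiw(full),
                              picp_s = comp$picp_s, mpiw_s = comp$mpiw_s)
    ## full-batch gradient-norm stopping check
    fwd <- net_forward(net, x, cache = TRUE)
    gb <- loss_soft_grad(interval_batch(fwd$out[, 1], fwd$out[, 2], y),
                         lam, eta, alpha, s)
    grads <- net_backward(net, fwd, cbind(gb$dlower, gb$dupper))
    gn <- sqrt(sum(unlist(lapply(grads, function(l)
      c(as.numeric(l$W), l$b)))^2))
    if (gn < grad_tol) break
  }
  list(net = net, trace = do.call(rbind, trace[!vapply(trace, is.null, TRUE)]),
       guard_events = guard_events,
       params = list(lam = lam, eta = eta, alpha = alpha, s = s,
                     lr = lr, decay = decay, epochs = epochs,
                     batch_size = batch_size))
}

#' Train an interval network on the LUBE loss by a genetic algorithm
#'
#' Evolves flattened network weight vectors (chromosomes) against fitness
#' `-Loss_L` evaluated on the full training set with step weight gamma = 1.
#' Generations apply rank selection of the top parents, single-point
#' crossover, and random-reset mutation of a percentage of genes; the best
#' individual always survives (elitism of 1), so the best loss trace is
#' non-increasing. Weight genes reset within `±gene_range`; the two
#' output-bias genes reset within the target range so the interval can
#' reach the data.
#'
#' @inheritParams train_soft_gd
#' @param eta,mu LUBE-loss hyperparameters (see [loss_lube()]);
#'   `target_range` is taken from the data, `max(y) - min(y)`.
#' @param n_solutions Population size (published range 10-20).
#' @param n_parents_mating Number of parents kept each generation (5-10).
#' @param mutation_percent_genes Percent of genes mutated per offspring
#'   (10-20).
#' @param n_generations Generation budget.
#' @param gene_range Reset half-width for weight genes.
#' @return A list with the trained `net`, a per-generation `trace`
#'   data.frame (`generation`, `best_loss`, `picp`, `mpiw`), and the final
#'   population.
#' @export
train_lube_ga <- function(x, y, hidden = c(16L), activation = "relu",
                          eta = 50, mu = 0.9,
                          n_solutions = 15L, n_parents_mating = 6L,
                          mutation_percent_genes = 15,
                          n_generations = 100L, gene_range = 1,
                          seed = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(n == length(y))
  if (n_parents_mating > n_solutions)
    stop("n_parents_mating must not exceed n_solutions")
  target_range <- max(y) - min(y)
  if (target_range <= 0) stop("degenerate target range")
  seed_rng(seed)

  template <- interval_net(ncol(x), hidden, activation, targets = y)
  n_genes <- length(net_flatten(template))
  ## per-gene reset bounds: weights in ±gene_range, output biases span y
  lo <- rep(-gene_range, n_genes)
  hi <- rep(gene_range, n_genes)
  bias_idx <- c(n_genes - 1L, n_genes)
  lo[bias_idx] <- min(y) - 0.5
  hi[bias_idx] <- max(y) + 0.5

  pop <- t(vapply(seq_len(n_solutions), function(i) {
    g <- stats::runif(n_genes, lo, hi) * 0.2      # start small
    g[bias_idx] <- stats::quantile(y, c(0.25, 0.75), names = FALSE) +
      stats::runif(2, -0.2, 0.2)
    g
  }, numeric(n_genes)))

  ## candidates whose bounds cross on average have negative mean width;
  ## the LUBE loss would reward them without bound (negative width times a
  ## large coverage penalty), so they are rejected as infeasible
  eval_loss <- function(theta) {
    net <- net_unflatten(template, theta)
    out <- net_forward(net, x)
    batch <- interval_batch(out[, 1], out[, 2], y)
    if (mpiw(batch) <= 0) return(Inf)
    loss_lube(batch, target_range, eta, mu, training = TRUE)
  }

  losses <- apply(pop, 1, eval_loss)
  trace <- vector("list", n_generations)
  n_mut <- max(1L, round(n_genes * mutation_percent_genes / 100))

  for (gen in seq_len(n_generations)) {
    ord <- order(losses)
    parents <- pop[ord[seq_len(n_parents_mating)], , drop = FALSE]
    elite <- pop[ord[1L], ]
    elite_loss <- losses[ord[1L]]
    ## offspring fill the rest of the population
    children <- matrix(NA_real_, n_solutions - 1L, n_genes)
    for (i in seq_len(nrow(children))) {
      pair <- sample.int(n_parents_mating, 2L, replace = n_parents_mating < 2L)
      cut <- sample.int(n_genes - 1L, 1L)
      child <- c(parents[pair[1L], seq_len(cut)],
                 parents[pair[2L], (cut + 1L):n_genes])
      mut <- sample.int(n_genes, n_mut)
      child[mut] <- stats::runif(n_mut, lo[mut], hi[mut])
      children[i, ] <- child
    }
    pop <- rbind(elite, children, deparse.level = 0)
    losses <- c(elite_loss, apply(children, 1, eval_loss))
    best <- which.min(losses)
    net_best <- net_unflatten(template, pop[best, ])
    out <- net_forward(net_best, x)
    batch <- interval_batch(out[, 1], out[, 2], y)
    trace[[gen]] <- data.frame(generation = gen, best_loss = losses[best],
                               picp = picp(batch), mpiw = mpiw(batch))
  }
  best <- which.min(losses)
  list(net = net_unflatten(template, pop[best, ]),
       trace = do.call(rbind, trace),
       population = pop,
       params = list(eta = eta, mu = mu, target_range = target_range,
                     n_solutions = n_solutions,
                     n_parents_mating = n_parents_mating,
                     mutation_percent_genes = mutation_percent_genes,
                     n_generations = n_generations))
}

#' Bootstrap-ensemble prediction intervals
#'
#' The baseline method: B single-output regression networks are trained on
#' bootstrap resamples of the training data; the ensemble mean estimates
#' the regression function and the ensemble variance the model (epistemic)
#' uncertainty. The noise (aleatoric) variance is estimated as the mean
#' squared training residual of the ensemble mean minus the mean model
#' variance, floored at zero, so predictive variance decomposes as
#' `sigma_y^2 = sigma_model^2 + sigma_noise^2`. Bounds are the Gaussian
#' interval `mean ± z_(1-alpha/2) * sigma_y`, symmetric by construction.
#'
#' @param x_train,y_train Training features (normalized) and targets.
#' @param x_test Features to predict intervals for.
#' @param B Number of bootstrap models (>= 2).
#' @param level Nominal coverage 1 - alpha.
#' @param size Hidden-layer size of each point regressor.
#' @param decay,maxit Weight decay and iteration cap passed to
#'   [nnet::nnet()].
#' @param seed Optional integer seed.
#' @return A list with `lower`, `upper`, `mean` (ensemble mean on test),
#'   `sigma_model`, `sigma_noise`, and the fitted `models`.
#' @export
bootstrap_pi <- function(x_train, y_train, x_test, B = 30L, level = 0.9,
                         size = 8L, decay = 1e-3, maxit = 200L, seed = NULL) {
  if (B < 2) stop("B must be >= 2 for a nonzero model variance")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  x_train <- as.matrix(x_train); x_test <- as.matrix(x_test)
  n <- nrow(x_train)
  seed_rng(seed)
  models <- vector("list", B)
  pred_test <- matrix(NA_real_, nrow(x_test), B)
  pred_train <- matrix(NA_real_, n, B)
  for (b in seq_len(B)) {
    rows <- sample.int(n, n, replace = TRUE)
    fit <- nnet::nnet(x_train[rows, , drop = FALSE], y_train[rows],
                      size = size, linout = TRUE, decay = decay,
                      maxit = maxit, trace = FALSE)
    models[[b]] <- fit
    pred_test[, b] <- as.numeric(stats::predict(fit, x_test))
    pred_train[, b] <- as.numeric(stats::predict(fit, x_train))
  }
  mean_test <- rowMeans(pred_test)
  var_model_test <- apply(pred_test, 1, stats::var)
  mean_train <- rowMeans(pred_train)
  var_model_train <- apply(pred_train, 1, stats::var)
  resid2 <- (y_train - mean_train)^2
  sigma2_noise <- max(0, mean(resid2) - mean(var_model_train))
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(var_model_test + sigma2_noise)
  list(lower = mean_test - half, upper = mean_test + half,
       mean = mean_test,
       sigma_model = sqrt(var_model_test),
       sigma_noise = sqrt(sigma2_noise),
       level = level, models = models)
}
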