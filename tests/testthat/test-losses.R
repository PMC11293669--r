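test_that("LUBE loss follows the width-times-penalty form", {
  ## batch with PICP = 0.8, MPIW = 2: widths 2, four of five covered
  b <- interval_batch(rep(0, 5), rep(2, 5), c(1, 1, 1, 1, 3))
  expect_equal(picp(b), 0.8)
  expect_equal(mpiw(b), 2)
  ## evaluation mode with PICP >= mu: loss is exactly MPIW / R
  expect_equal(loss_lube(b, 4, eta = 50, mu = 0.8, training = FALSE), 0.5)
  ## training mode at PICP = mu: exponent zero, loss doubles
  expect_equal(loss_lube(b, 4, eta = 50, mu = 0.8, training = TRUE), 1)
  ## direct arithmetic: 0.5 * (1 + e^5)
  expect_equal(loss_lube(b, 4, eta = 50, mu = 0.9, training = TRUE),
               0.5 * (1 + exp(5)))
  expect_equal(0.5 * (1 + exp(5)), 74.71, tolerance = 1e-3)
  expect_error(loss_lube(b, 0, 50, 0.9), "target_range")
})

test_that("LUBE loss is monotone in coverage and width", {
  ## fixed widths, increasing coverage
  losses <- sapply(0:5, function(ncov) {
    target <- c(rep(1, ncov), rep(9, 5 - ncov))
    loss_lube(interval_batch(rep(0, 5), rep(2, 5), target), 4,
              eta = 30, mu = 0.9, training = TRUE)
  })
  expect_true(all(diff(losses) < 0))
  ## fixed coverage, increasing width
  losses_w <- sapply(c(1, 2, 3), function(w)
    loss_lube(interval_batch(rep(0, 4), rep(w, 4), rep(0.5, 4)), 4,
              eta = 30, mu = 0.9, training = TRUE))
  expect_true(all(diff(losses_w) > 0))
})

test_that("soft loss matches independent arithmetic and its guards", {
  b <- random_batch(60, 2)
  for (s in c(10, 80)) {
    got <- loss_soft(b, lam = 12, eta = 70, alpha = 0.15, s = s)
    ref <- loss_soft_reference(b$lower, b$upper, b$target, 12, 70, 0.15, s)
    expect_equal(got, ref, tolerance = 1e-12)
  }
  ## with coverage above nominal the loss is the captured width alone
  cover <- interval_batch(b$target - 2, b$target + 2, b$target)
  expect_equal(loss_soft(cover, 10, 100, 0.4, 50), mpiw_captured(cover))
  ## lambda = 0 removes the penalty entirely
  expect_equal(loss_soft(b, 0, 100, 0.1, 50),
               mpiw_captured(b))
  ## direct arithmetic scale check: penalty = lam * eta/(a(1-a)) * shortfall^2
  comp <- loss_soft_components(b, 10, 100, 0.1, 50)
  short <- max(0, 0.9 - comp$picp_s)
  expect_equal(comp$loss - comp$mpiw_s, 10 * (100 / 0.09) * short^2,
               tolerance = 1e-10)
  expect_error(loss_soft(b, -1, 100, 0.1, 50), "lam")
  expect_error(loss_soft(b, 1, 100, 1.5, 50), "alpha")
})

test_that("soft penalty is zero above nominal, positive and decreasing below", {
  set.seed(3)
  target <- runif(100, 0, 4)
  penalty_at <- function(half) {
    b <- interval_batch(target - half, target + half, target)
    comp <- loss_soft_components(b, 10, 100, 0.05, 20)
    comp$loss - comp$mpiw_s
  }
  p <- sapply(c(0.01, 0.05, 0.1, 0.15), penalty_at)
  expect_true(all(diff(p) < 0))          # widening reduces the penalty
  expect_gt(p[4], 0)
  expect_equal(penalty_at(2), 0)         # fully covered: no penalty
})

test_that("zero-capture guard falls back to the plain mean width", {
  none <- interval_batch(c(0, 0), c(1, 2), c(5, 6))
  comp <- loss_soft_components(none, 5, 50, 0.1, 10)
  expect_true(comp$guard)
  expect_equal(comp$mpiw_s, 1.5)
})

test_that("analytic soft-loss gradient matches central differences", {
  h <- 1e-6
  for (seed in 1:10) {
    b <- random_batch(30, seed)
    lam <- 5 + seed; eta <- 60; alpha <- 0.12; s <- 15 + 2 * seed
    g <- loss_soft_grad(b, lam, eta, alpha, s)
    ## hold the hard-capture selector fixed: perturbations stay local
    for (i in c(1, 17, 30)) {
      for (side in c("lower", "upper")) {
        up <- b; dn <- b
        up[[side]][i] <- up[[side]][i] + h
        dn[[side]][i] <- dn[[side]][i] - h
        fd <- (loss_soft_reference(up$lower, up$upper, up$target,
                                   lam, eta, alpha, s) -
                 loss_soft_reference(dn$lower, dn$upper, dn$target,
                                     lam, eta, alpha, s)) / (2 * h)
        ana <- if (side == "lower") g$dlower[i] else g$dupper[i]
        denom <- max(abs(fd), 1e-8)
        expect_lt(abs(ana - fd) / denom, 1e-4)
      }
    }
  }
})
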