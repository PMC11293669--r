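#' LUBE coverage-width loss (Loss_L)
#'
#' The lower-upper-bound estimation loss: normalized mean width scaled by
#' an exponential coverage penalty,
#' `(MPIW / R) * (1 + gamma * exp(-eta * (PICP - mu)))`.
#' During training the step weight `gamma` is fixed at 1; at evaluation
#' `gamma = 0` when PICP >= mu and 1 otherwise.
#'
#' @param batch An [interval_batch()].
#' @param target_range Target range R (> 0).
#' @param eta Penalty sharpness (amplifies the coverage shortfall).
#' @param mu Nominal confidence level 1 - alpha.
#' @param training If `TRUE` use gamma = 1; otherwise the evaluation step
#'   rule.
#' @return Scalar loss.
#' @examples
#' b <- interval_batch(c(0, 0), c(2, 1), c(1, 2))
#' loss_lube(b, target_range = 4, eta = 50, mu = 0.9)
#' @export
loss_lube <- function(batch, target_range, eta, mu, training = TRUE) {
  if (target_range <= 0) stop("target_range must be > 0")
  if (mu <= 0 || mu >= 1) stop("mu must be in (0, 1)")
  if (eta <= 0) stop("eta must be > 0")
  p <- picp(batch)
  gam <- if (training) 1 else as.numeric(p < mu)
  (mpiw(batch) / target_range) * (1 + gam * exp(-eta * (p - mu)))
}

#' Soft coverage-width loss (Loss_S) and its components
#'
#' The differentiable interval loss
#' `MPIW_S + lambda * (eta / (alpha (1 - alpha))) * max(0, (1 - alpha) - PICP_S)^2`
#' with [picp_soft()] as the softened coverage and [mpiw_captured()] as the
#' captured-only width. If a batch captures no point (possible early in
#' training), the width term falls back to the plain mean width so the loss
#' stays defined; the fallback is flagged in the returned components.
#'
#' @param batch An [interval_batch()].
#' @param lam Lagrangian weight of the coverage penalty (>= 0).
#' @param eta Constant penalty scale (a free hyperparameter, not the
#'   minibatch length).
#' @param alpha Miscoverage rate; the nominal level is 1 - alpha.
#' @param s Softening factor for the coverage sigmoids (> 0).
#' @return `loss_soft` returns the scalar loss; `loss_soft_components`
#'   returns a list with `loss`, `picp_s`, `mpiw_s`, `n_captured` and
#'   `guard` (TRUE when the zero-capture fallback was used).
#' @export
loss_soft <- function(batch, lam, eta, alpha, s) {
  loss_soft_components(batch, lam, eta, alpha, s)$loss
}

#' @rdname loss_soft
#' @export
loss_soft_components <- function(batch, lam, eta, alpha, s) {
  if (lam < 0) stop("lam must be >= 0")
  if (eta <= 0) stop("eta must be > 0")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (s <= 0) stop("s must be > 0")
  k <- hard_capture(batch)
  n_cap <- sum(k)
  guard <- n_cap == 0
  width <- batch$upper - batch$lower
  mpiw_s <- if (guard) mean(width) else sum(k * width) / n_cap
  p_s <- picp_soft(batch, s)
  shortfall <- max(0, (1 - alpha) - p_s)
  penalty <- lam * (eta / (alpha * (1 - alpha))) * shortfall^2
  list(loss = mpiw_s + penalty, picp_s = p_s, mpiw_s = mpiw_s,
       n_captured = n_cap, guard = guard)
}

#' Gradient of Loss_S with respect to the interval bounds
#'
#' Analytic partial derivatives of [loss_soft()] with respect to each
#' observation's lower and upper bound, holding the hard-capture selector
#' inside MPIW_S fixed (the loss is differentiable everywhere except at
#' that selector). Used by the gradient-descent trainer's backward pass.
#'
#' @inheritParams loss_soft
#' @return A list with numeric vectors `dlower` and `dupper`.
#' @export
loss_soft_grad <- function(batch, lam, eta, alpha, s) {
  k <- hard_capture(batch)
  n <- length(k)
  n_cap <- sum(k)
  if (n_cap == 0) {          # zero-capture fallback: plain mean width
    d_w_upper <- rep(1 / n, n)
  } else {
    d_w_upper <- k / n_cap
  }
  d_w_lower <- -d_w_upper

  a <- sigmoid(s * (batch$target - batch$lower))
  b <- sigmoid(s * (batch$upper - batch$target))
  p_s <- mean(a * b)
  shortfall <- (1 - alpha) - p_s
  if (shortfall > 0) {
    dpen_dp <- -2 * lam * (eta / (alpha * (1 - alpha))) * shortfall
    dp_dlower <- -s * a * (1 - a) * b / n
    dp_dupper <- s * a * b * (1 - b) / n
    d_w_lower <- d_w_lower + dpen_dp * dp_dlower
    d_w_upper <- d_w_upper + dpen_dp * dp_dupper
  }
  list(dlower = d_w_lower, dupper = d_w_upper)
}
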