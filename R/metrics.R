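#' Bundle prediction-interval bounds with their targets
#'
#' An interval batch holds, per observation, the lower bound L(x_i), upper
#' bound U(x_i) and observed target y_i. Crossed bounds (upper < lower) are
#' legal — training may transiently produce them — and their fraction is
#' reported by [crossing_fraction()] rather than silently repaired.
#'
#' @param lower,upper,target Equal-length finite numeric vectors.
#' @return An object of class `interval_batch`.
#' @export
interval_batch <- function(lower, upper, target) {
  n <- length(target)
  if (n == 0L) stop("empty interval batch")
  if (length(lower) != n || length(upper) != n)
    stop("lower, upper and target must have equal length")
  if (!all(is.finite(lower), is.finite(upper), is.finite(target)))
    stop("interval batch entries must be finite")
  structure(list(lower = as.numeric(lower), upper = as.numeric(upper),
                 target = as.numeric(target)),
            class = "interval_batch")
}

#' @export
print.interval_batch <- function(x, ...) {
  cat("Interval batch:", length(x$target), "observations, PICP",
      sprintf("%.3f", picp(x)), "MPIW", sprintf("%.3f", mpiw(x)),
      sprintf("(%.1f%% crossed)\n", 100 * crossing_fraction(x)))
  invisible(x)
}

hard_capture <- function(batch) {
  as.numeric(batch$lower <= batch$target & batch$target <= batch$upper)
}

#' Prediction interval coverage probability (PICP)
#'
#' Fraction of targets covered by their interval; a target exactly on a
#' bound counts as covered (inclusive at both ends).
#'
#' @param batch An [interval_batch()].
#' @return A probability in \[0, 1\].
#' @examples
#' picp(interval_batch(c(0, 0, 2), c(2, 1, 4), c(1, 2, 3)))  # 2/3
#' @export
picp <- function(batch) {
  stopifnot(inherits(batch, "interval_batch"))
  mean(hard_capture(batch))
}

#' Mean prediction interval width (MPIW)
#'
#' Mean of `upper - lower`. May be negative when bounds cross; crossed
#' bounds are reported, never clipped, inside the metric.
#'
#' @param batch An [interval_batch()].
#' @return Mean width (target units).
#' @export
mpiw <- function(batch) {
  stopifnot(inherits(batch, "interval_batch"))
  mean(batch$upper - batch$lower)
}

#' Normalized mean prediction interval width (NMPIW)
#'
#' `mpiw / R` where `R = max(y) - min(y)` is the target range; for the
#' 0-4 pain scale, R = 4.
#'
#' @param mpiw Mean interval width.
#' @param target_range Target range R (> 0).
#' @return Dimensionless normalized width.
#' @examples
#' nmpiw(2.28, 4)  # 0.57
#' @export
nmpiw <- function(mpiw, target_range) {
  if (!is.numeric(target_range) || target_range <= 0)
    stop("target_range must be > 0")
  mpiw / target_range
}

#' Sigmoid-softened coverage probability (PICP_S)
#'
#' Replaces the hard capture indicator with the product of two logistic
#' sigmoids per observation, `sigmoid(s (y - L)) * sigmoid(s (U - y))`,
#' averaged over the batch. Converges to the hard [picp()] as the
#' softening factor `s` grows (for targets not exactly on a bound).
#'
#' @param batch An [interval_batch()].
#' @param s Softening factor (> 0); larger means closer to the hard
#'   indicator.
#' @return A value in (0, 1).
#' @export
picp_soft <- function(batch, s) {
  stopifnot(inherits(batch, "interval_batch"))
  if (!is.numeric(s) || s <= 0) stop("softening factor s must be > 0")
  mean(sigmoid(s * (batch$target - batch$lower)) *
         sigmoid(s * (batch$upper - batch$target)))
}

#' Captured-only mean interval width (MPIW_S)
#'
#' Mean width over the captured observations only (hard capture,
#' `L <= y <= U`), removing the influence of points the interval misses.
#' Errors when no point is captured; training code guards this case
#' separately (see [loss_soft()]).
#'
#' @param batch An [interval_batch()].
#' @return Mean width over captured points.
#' @export
mpiw_captured <- function(batch) {
  stopifnot(inherits(batch, "interval_batch"))
  k <- hard_capture(batch)
  if (sum(k) == 0) stop("no captured points: MPIW over captured set undefined")
  sum(k * (batch$upper - batch$lower)) / sum(k)
}

#' Fraction of crossed intervals
#'
#' Fraction of observations with `upper < lower`.
#'
#' @param batch An [interval_batch()].
#' @return A probability in \[0, 1\].
#' @export
crossing_fraction <- function(batch) {
  stopifnot(inherits(batch, "interval_batch"))
  mean(batch$upper < batch$lower)
}

#' Summarize interval quality at a nominal level
#'
#' @param batch An [interval_batch()].
#' @param target_range Target range R used for NMPIW.
#' @param nominal Nominal coverage 1 - alpha the bounds aim for.
#' @return A one-row `data.frame`: nominal, picp, mpiw, nmpiw,
#'   crossing_fraction.
#' @export
pi_quality <- function(batch, target_range, nominal) {
  w <- mpiw(batch)
  data.frame(nominal = nominal,
             picp = picp(batch),
             mpiw = w,
             nmpiw = nmpiw(w, target_range),
             crossing_fraction = crossing_fraction(batch))
}
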