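#' Fit a prediction-interval model
#'
#' The package's front end: fits an interval model for a continuous target
#' at a nominal coverage level by one of three methods —
#' `"soft"` (two-output network trained on the soft coverage-width loss by
#' minibatch Adam), `"lube"` (same network trained on the LUBE loss by a
#' genetic algorithm) or `"bootstrap"` (ensemble of point regressors with
#' Gaussian variance-decomposition intervals). Features are min-max
#' normalized internally; the fitted scaler is stored and re-applied by
#' `predict`.
#'
#' @param x Feature matrix/data.frame, or a formula.
#' @param y Target vector (default method).
#' @param method `"soft"`, `"lube"` or `"bootstrap"`.
#' @param level Nominal coverage 1 - alpha.
#' @param hidden Hidden-layer sizes of the interval network.
#' @param activation Hidden activation function.
#' @param control Named list overriding trainer defaults (passed to
#'   [train_soft_gd()], [train_lube_ga()] or [bootstrap_pi()]; e.g.
#'   `list(epochs = 200, s = 120)`).
#' @param seed Optional integer seed; the fit is deterministic given it.
#' @param ... Passed between methods.
#' @return An object of class `pinet` with `print`, `summary`, `coef`,
#'   `predict`, `plot` and `residuals` methods.
#' @examples
#' d <- simulate_known_quantiles(300, seed = 1)
#' fit <- pinet(d["x"], d$y, method = "soft", level = 0.9,
#'              hidden = 8, control = list(epochs = 40), seed = 1)
#' print(fit)
#' head(predict(fit, d["x"]))
#' @export
pinet <- function(x, ...) UseMethod("pinet")

#' @rdname pinet
#' @param data Data frame holding the formula variables.
#' @export
pinet.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data)
  y <- stats::model.response(mf)
  terms_ <- attr(mf, "terms")
  xm <- stats::model.matrix(terms_, mf)
  xm <- xm[, colnames(xm) != "(Intercept)", drop = FALSE]
  fit <- pinet.default(xm, y, ...)
  fit$terms <- terms_
  fit$call <- match.call()
  fit
}

#' @rdname pinet
#' @export
pinet.default <- function(x, y, method = c("soft", "lube", "bootstrap"),
                          level = 0.9, hidden = c(32L),
                          activation = "relu", control = list(),
                          seed = NULL, ...) {
  method <- match.arg(method)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  x <- as_feature_mat(x)
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y))
  scaler <- fit_minmax(x)
  xs <- predict(scaler, x)

  fit <- switch(method,
    soft = {
      args <- utils::modifyList(
        list(x = xs, y = y, hidden = hidden, activation = activation,
             alpha = 1 - level, seed = seed), control)
      do.call(train_soft_gd, args)
    },
    lube = {
      args <- utils::modifyList(
        list(x = xs, y = y, hidden = hidden, activation = activation,
             mu = level, seed = seed), control)
      do.call(train_lube_ga, args)
    },
    bootstrap = {
      args <- utils::modifyList(
        list(x_train = xs, y_train = y, x_test = xs, level = level,
             seed = seed), control)
      do.call(bootstrap_pi, args)
    })

  obj <- structure(list(method = method, level = level, scaler = scaler,
                        features = colnames(x), x = x, y = y,
                        call = match.call(), seed = seed),
                   class = "pinet")
  if (method == "bootstrap") {
    obj$ensemble <- fit
    train_batch <- interval_batch(fit$lower, fit$upper, y)
  } else {
    obj$net <- fit$net
    obj$trace <- fit$trace
    obj$train_params <- fit$params
    if (method == "soft") obj$guard_events <- fit$guard_events
    train_batch <- predict_bounds(fit$net, xs, y)
  }
  obj$train_quality <- pi_quality(train_batch, max(y) - min(y), level)
  obj
}

pinet_bounds <- function(object, newdata) {
  xs <- predict(object$scaler, as_feature_mat(newdata))
  if (object$method == "bootstrap") {
    e <- object$ensemble
    pred <- vapply(e$models,
                   function(m) as.numeric(stats::predict(m, xs)),
                   numeric(nrow(xs)))
    pred <- matrix(pred, nrow = nrow(xs))
    mu <- rowMeans(pred)
    vm <- apply(pred, 1, stats::var)
    z <- stats::qnorm(1 - (1 - object$level) / 2)
    half <- z * sqrt(vm + e$sigma_noise^2)
    cbind(lower = mu - half, upper = mu + half)
  } else {
    b <- predict_bounds(object$net, xs)
    colnames(b) <- c("lower", "upper")
    b
  }
}

#' Predict interval bounds from a fitted pinet model
#'
#' Returns per-row lower and upper bounds. By default crossed bounds
#' (upper < lower, possible for the free two-output networks) are swapped
#' into canonical order at this reporting step — never inside training —
#' and the pre-swap crossing fraction is attached as an attribute.
#'
#' @param object A fitted [pinet()] model.
#' @param newdata Features to predict for (omit to reuse training data is
#'   not supported; supply explicitly).
#' @param canonical Swap crossed bounds into (min, max) order.
#' @param ... Unused.
#' @return A `data.frame` with columns `lower` and `upper`; attribute
#'   `crossing_fraction` gives the fraction of rows whose raw bounds were
#'   crossed.
#' @export
predict.pinet <- function(object, newdata, canonical = TRUE, ...) {
  if (!is.null(object$terms) && is.data.frame(newdata)) {
    tt <- stats::delete.response(object$terms)
    mf <- stats::model.frame(tt, newdata)
    xm <- stats::model.matrix(tt, mf)
    newdata <- xm[, colnames(xm) != "(Intercept)", drop = FALSE]
  }
  b <- pinet_bounds(object, newdata)
  crossed <- b[, "upper"] < b[, "lower"]
  out <- data.frame(lower = b[, "lower"], upper = b[, "upper"])
  if (canonical && any(crossed)) {
    lo <- pmin(out$lower, out$upper)
    hi <- pmax(out$lower, out$upper)
    out$lower <- lo; out$upper <- hi
  }
  attr(out, "crossing_fraction") <- mean(crossed)
  out
}

#' @export
print.pinet <- function(x, ...) {
  cat("Prediction-interval model (", x$method, "), nominal level ",
      format(x$level), "\n", sep = "")
  if (!is.null(x$net)) print(x$net)
  else cat("Bootstrap ensemble of", length(x$ensemble$models),
           "point regressors\n")
  q <- x$train_quality
  cat(sprintf("Training PICP %.3f, MPIW %.3f, NMPIW %.3f\n",
              q$picp, q$mpiw, q$nmpiw))
  invisible(x)
}

#' @export
summary.pinet <- function(object, ...) {
  structure(list(method = object$method, level = object$level,
                 quality = object$train_quality,
                 trace_tail = if (!is.null(object$trace))
                   utils::tail(object$trace, 5),
                 guard_events = object$guard_events,
                 n_train = length(object$y),
                 features = object$features),
            class = "summary.pinet")
}

#' @export
print.summary.pinet <- function(x, ...) {
  cat("pinet fit:", x$method, "at nominal level", format(x$level),
      "on", x$n_train, "observations,", length(x$features), "features\n")
  cat("Training interval quality:\n")
  print(x$quality, row.names = FALSE)
  if (!is.null(x$trace_tail)) {
    cat("Last training-trace entries:\n")
    print(x$trace_tail, row.names = FALSE)
  }
  if (!is.null(x$guard_events) && x$guard_events > 0)
    cat("Zero-capture width fallback used in", x$guard_events,
        "minibatches\n")
  invisible(x)
}

#' @export
coef.pinet <- function(object, ...) {
  if (is.null(object$net)) {
    message("bootstrap ensembles have no single weight vector")
    return(invisible(NULL))
  }
  net_flatten(object$net)
}

#' Interval residuals
#'
#' Signed distance of each training target outside its interval: 0 when
#' covered, `y - lower` (negative) below, `y - upper` (positive) above.
#'
#' @param object A fitted [pinet()] model.
#' @param newdata,y Optional evaluation features and targets; defaults to
#'   the training data.
#' @param ... Unused.
#' @return Numeric vector of exceedances.
#' @export
residuals.pinet <- function(object, newdata = NULL, y = NULL, ...) {
  if (is.null(newdata)) {
    newdata <- object$x
    y <- object$y
  }
  if (is.null(y)) stop("supply y alongside newdata")
  b <- predict.pinet(object, newdata)
  ifelse(y < b$lower, y - b$lower, ifelse(y > b$upper, y - b$upper, 0))
}

#' Plot the training trace of a pinet fit
#'
#' For the optimized methods, plots the loss trace (epoch or generation)
#' and the evolution of training PICP against the nominal level.
#'
#' @param x A fitted [pinet()] model.
#' @param ... Passed to [plot()].
#' @export
plot.pinet <- function(x, ...) {
  if (is.null(x$trace)) {
    graphics::hist(x$ensemble$upper - x$ensemble$lower,
                   main = "Bootstrap interval widths", xlab = "width")
    return(invisible(x))
  }
  tr <- x$trace
  step <- if ("epoch" %in% names(tr)) tr$epoch else tr$generation
  loss <- if ("loss" %in% names(tr)) tr$loss else tr$best_loss
  old <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(old))
  plot(step, loss, type = "l", xlab = "step", ylab = "loss",
       main = paste(x$method, "training loss"), ...)
  plot(step, tr$picp, type = "l", xlab = "step", ylab = "PICP",
       ylim = c(0, 1), main = "training coverage")
  graphics::abline(h = x$level, lty = 2)
  invisible(x)
}
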