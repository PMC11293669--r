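#' Create an interval-output feed-forward network
#'
#' A fully connected network with `input_dim` inputs, the given hidden
#' layers, and exactly two linear output neurons: the first emits the
#' lower bound, the second the upper bound of the prediction interval.
#' Hidden and output weights are initialized small uniform under the seed;
#' the two output biases start at the 25% and 75% quantiles of the
#' training targets (when supplied) so the initial interval sits inside
#' the data range and the coverage sigmoids are not saturated at large
#' softening factors.
#'
#' @param input_dim Number of input features.
#' @param hidden Integer vector of hidden-layer sizes (1-4 layers of
#'   10-150 neurons in the published search space).
#' @param activation Hidden activation: `"relu"`, `"tanh"` or `"linear"`.
#' @param targets Optional training targets used to place the initial
#'   output biases.
#' @param init_scale Half-width of the uniform weight initialization.
#' @param seed Optional integer seed.
#' @return An object of class `interval_net` (list of weight matrices
#'   `W`, bias vectors `b`, and the activation name).
#' @export
interval_net <- function(input_dim, hidden = c(32L), activation = c("relu", "tanh", "linear"),
                         targets = NULL, init_scale = 0.1, seed = NULL) {
  activation <- match.arg(activation)
  stopifnot(input_dim >= 1, all(hidden >= 1))
  seed_rng(seed)
  sizes <- c(input_dim, hidden, 2L)
  layers <- vector("list", length(sizes) - 1L)
  for (i in seq_along(layers)) {
    layers[[i]] <- list(
      W = matrix(stats::runif(sizes[i] * sizes[i + 1L], -init_scale, init_scale),
                 nrow = sizes[i]),
      b = stats::runif(sizes[i + 1L], -init_scale, init_scale))
  }
  if (!is.null(targets)) {
    q <- stats::quantile(targets, c(0.25, 0.75), names = FALSE)
    layers[[length(layers)]]$b <- c(q[1], q[2])
  }
  structure(list(layers = layers, activation = activation,
                 input_dim = as.integer(input_dim),
                 hidden = as.integer(hidden)),
            class = "interval_net")
}

act_fun <- function(z, activation) {
  switch(activation,
         relu = pmax(z, 0),
         tanh = tanh(z),
         linear = z)
}

act_grad <- function(z, activation) {
  switch(activation,
         relu = (z > 0) * 1,
         tanh = 1 - tanh(z)^2,
         linear = array(1, dim = dim(z)))
}

## forward pass; with cache = TRUE also returns pre-activations and
## layer inputs for backpropagation
net_forward <- function(net, x, cache = FALSE) {
  x <- as.matrix(x)
  if (ncol(x) != net$input_dim)
    stop("input has ", ncol(x), " columns; network expects ", net$input_dim)
  n_layers <- length(net$layers)
  inputs <- vector("list", n_layers)
  pre <- vector("list", n_layers)
  h <- x
  for (i in seq_len(n_layers)) {
    inputs[[i]] <- h
    z <- sweep(h %*% net$layers[[i]]$W, 2, net$layers[[i]]$b, "+")
    pre[[i]] <- z
    h <- if (i < n_layers) act_fun(z, net$activation) else z  # linear output
  }
  if (cache) list(out = h, inputs = inputs, pre = pre) else h
}

## backpropagate d(loss)/d(output) to parameter gradients
net_backward <- function(net, fwd, dout) {
  n_layers <- length(net$layers)
  grads <- vector("list", n_layers)
  delta <- dout
  for (i in rev(seq_len(n_layers))) {
    grads[[i]] <- list(W = crossprod(fwd$inputs[[i]], delta),
                       b = colSums(delta))
    if (i > 1L) {
      delta <- (delta %*% t(net$layers[[i]]$W)) *
        act_grad(fwd$pre[[i - 1L]], net$activation)
    }
  }
  grads
}

## flatten parameters to a single vector (GA chromosome) and back
net_flatten <- function(net) {
  unlist(lapply(net$layers, function(l) c(as.numeric(l$W), l$b)),
         use.names = FALSE)
}

net_unflatten <- function(net, theta) {
  pos <- 0L
  for (i in seq_along(net$layers)) {
    nw <- length(net$layers[[i]]$W)
    nb <- length(net$layers[[i]]$b)
    net$layers[[i]]$W[] <- theta[pos + seq_len(nw)]
    net$layers[[i]]$b <- theta[pos + nw + seq_len(nb)]
    pos <- pos + nw + nb
  }
  if (pos != length(theta)) stop("theta length mismatch")
  net
}

#' Predict interval bounds from a network
#'
#' Runs the forward pass and returns the two output neurons as lower and
#' upper bounds per row, bundled with the targets when supplied.
#'
#' @param net An [interval_net()].
#' @param x Feature matrix (already normalized with the training scaler).
#' @param target Optional targets; when given an [interval_batch()] is
#'   returned, otherwise a two-column matrix.
#' @return An `interval_batch` or a matrix with columns `lower`, `upper`.
#' @export
predict_bounds <- function(net, x, target = NULL) {
  out <- net_forward(net, x)
  if (is.null(target))
    return(structure(out, dimnames = list(NULL, c("lower", "upper"))))
  interval_batch(out[, 1], out[, 2], target)
}

#' @export
print.interval_net <- function(x, ...) {
  cat("Interval network:", x$input_dim, "inputs ->",
      paste(x$hidden, collapse = "-"), paste0("(", x$activation, ")"),
      "-> 2 linear outputs (lower, upper);",
      length(net_flatten(x)), "parameters\n")
  invisible(x)
}
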