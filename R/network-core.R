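#' Rectified linear unit
#'
#' `relu(x) = max(0, x)`, the activation used throughout the package.
#'
#' @param x Numeric vector, matrix or array.
#' @return `x` with every negative entry replaced by 0; the shape is
#'   preserved.
#' @export
relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' Evaluate the one-neuron composite network
#'
#' The scalar feedforward network with a single ReLU neuron:
#' `w2 * max(0, w1 * x + b1) + b2`. This is the smallest nontrivial
#' feedforward network, and the building block the wider single-hidden-layer
#' networks are assembled from.
#'
#' @param x Input (vectorized).
#' @param w1,b1 Input-side weight and bias.
#' @param w2,b2 Output-side weight and bias.
#' @return Numeric vector of network outputs.
#' @examples
#' eval_composite(1, w1 = 2, b1 = -1, w2 = 3, b2 = 0.5) # 3.5
#' @export
eval_composite <- function(x, w1, b1, w2, b2) {
  w2 * relu(w1 * x + b1) + b2
}

#' One-hidden-layer SIR network
#'
#' A feedforward network with a single input (time), `n_neurons` ReLU
#' hidden units and three linear outputs, one per SIR compartment. Output
#' channel `c` evaluates to
#' `sum_i W_out[c, i] * max(0, w_in[i] * t + b_in[i]) + b_out[c]`.
#' Parameters live in a flat registry with a stable positional ordering
#' (see [flatten_simple_net()]) so optimizers and tests can address them
#' by index.
#'
#' @param n_neurons Hidden width (typically 1 to 5).
#' @param w_in,b_in Hidden-layer weights and biases, length `n_neurons`.
#' @param W_out 3 x `n_neurons` output weight matrix (rows: S, I, R).
#' @param b_out Output biases, length 3.
#' @return An object of class `simple_net`.
#' @export
simple_net <- function(n_neurons, w_in, b_in, W_out, b_out) {
  stopifnot(length(w_in) == n_neurons, length(b_in) == n_neurons,
            is.matrix(W_out), nrow(W_out) == 3, ncol(W_out) == n_neurons,
            length(b_out) == 3)
  params <- c(w_in, b_in, W_out, b_out)
  if (!all(is.finite(params))) stop("network parameters must be finite", call. = FALSE)
  structure(list(n_neurons = as.integer(n_neurons), w_in = as.numeric(w_in),
                 b_in = as.numeric(b_in), W_out = W_out,
                 b_out = as.numeric(b_out)),
            class = "simple_net")
}

#' Flat parameter registry of a simple_net
#'
#' Ordering: per hidden neuron the affine pair `(w_in[i], b_in[i])`
#' (i = 1..K), then per output channel the affine block
#' `(W_out[c, 1..K], b_out[c])` (c = S, I, R). Total length
#' `2K + 3(K + 1)`.
#'
#' @param net A [simple_net()].
#' @return Numeric parameter vector.
#' @export
flatten_simple_net <- function(net) {
  K <- net$n_neurons
  hidden <- as.numeric(rbind(net$w_in, net$b_in))
  output <- as.numeric(t(cbind(net$W_out, net$b_out)))
  out <- c(hidden, output)
  stopifnot(length(out) == 2 * K + 3 * (K + 1))
  out
}

#' @rdname flatten_simple_net
#' @param params Flat parameter vector as produced by [flatten_simple_net()].
#' @param n_neurons Hidden width.
#' @export
unflatten_simple_net <- function(params, n_neurons) {
  K <- n_neurons
  stopifnot(length(params) == 2 * K + 3 * (K + 1))
  hidden <- matrix(params[seq_len(2 * K)], nrow = 2)
  output <- matrix(params[-seq_len(2 * K)], nrow = K + 1)
  simple_net(K, w_in = hidden[1, ], b_in = hidden[2, ],
             W_out = t(output[seq_len(K), , drop = FALSE]),
             b_out = output[K + 1, ])
}

#' Evaluate a simple_net on a time grid
#'
#' @param net A [simple_net()].
#' @param t Numeric vector of times (days).
#' @return A `length(t)` x 3 matrix with columns `S`, `I`, `R`. The map
#'   `t -> output` is continuous and piecewise linear.
#' @export
eval_simple_net <- function(net, t) {
  stopifnot(all(is.finite(t)))
  H <- relu(outer(t, net$w_in) + matrix(net$b_in, length(t), net$n_neurons,
                                        byrow = TRUE))
  out <- H %*% t(net$W_out) + matrix(net$b_out, length(t), 3, byrow = TRUE)
  colnames(out) <- c("S", "I", "R")
  out
}

#' Glorot (Xavier) uniform initialization of a dense network
#'
#' Draws each layer's weights uniformly on
#' `[-sqrt(6 / (fan_in + fan_out)), +sqrt(6 / (fan_in + fan_out))]` and
#' sets all biases to zero, balancing forward and backward signal scale.
#'
#' @param layer_widths Integer vector of layer widths including input and
#'   output, e.g. `c(1, 64, 64, 64, 3)`.
#' @param seed Integer seed; the draw is reproducible and leaves the
#'   caller's RNG state untouched.
#' @return A list with elements `W` (list of `out x in` weight matrices)
#'   and `b` (list of zero bias vectors), one per layer.
#' @export
glorot_uniform_init <- function(layer_widths, seed) {
  stopifnot(length(layer_widths) >= 2, all(layer_widths >= 1))
  draw <- function() {
    W <- vector("list", length(layer_widths) - 1)
    b <- vector("list", length(layer_widths) - 1)
    for (l in seq_along(W)) {
      fan_in <- layer_widths[l]
      fan_out <- layer_widths[l + 1]
      limit <- sqrt(6 / (fan_in + fan_out))
      W[[l]] <- matrix(stats::runif(fan_in * fan_out, -limit, limit),
                       nrow = fan_out, ncol = fan_in)
      b[[l]] <- rep(0, fan_out)
    }
    list(W = W, b = b)
  }
  with_local_seed(seed, draw())
}

#' Forward pass of a dense ReLU network of time
#'
#' Evaluates the fully connected network `u(t)`: input is the scalar time,
#' hidden layers apply ReLU, the output layer is linear with one unit per
#' SIR compartment. Also available is the exact derivative of each output
#' with respect to time, obtained by forward-mode differentiation through
#' the same activation pattern (the ReLU subgradient at 0 is taken as 0,
#' matching reverse-mode autodiff conventions).
#'
#' @param theta Parameter list with elements `W`, `b` as produced by
#'   [glorot_uniform_init()].
#' @param t Numeric vector of times.
#' @return For [eval_dense()], a `length(t)` x 3 matrix of outputs
#'   (columns `S`, `I`, `R`); for [dense_time_derivative()], the matching
#'   matrix of time derivatives.
#' @export
eval_dense <- function(theta, t) {
  dense_forward(theta, t)$u
}

#' @rdname eval_dense
#' @export
dense_time_derivative <- function(theta, t) {
  dense_forward(theta, t)$du
}

# Shared forward + tangent pass. Returns outputs and du/dt, both n x 3.
dense_forward <- function(theta, t) {
  stopifnot(all(is.finite(t)))
  L <- length(theta$W)
  A <- matrix(as.numeric(t), nrow = 1)        # activations, width x n
  V <- matrix(1, nrow = 1, ncol = length(t))  # tangent d(activation)/dt
  for (l in seq_len(L - 1)) {
    Z <- theta$W[[l]] %*% A + theta$b[[l]]
    mask <- Z > 0
    A <- Z * mask
    V <- (theta$W[[l]] %*% V) * mask
  }
  u <- theta$W[[L]] %*% A + theta$b[[L]]
  du <- theta$W[[L]] %*% V
  u <- t(u); du <- t(du)
  colnames(u) <- colnames(du) <- c("S", "I", "R")
  list(u = u, du = du)
}

#' Serialize network parameters to a name,value table
#'
#' Mirrors a spreadsheet-style parameters table: one row per scalar
#' parameter with a stable name encoding its position.
#'
#' @param net A [simple_net()].
#' @return A tibble with columns `name`, `value`.
#' @export
simple_net_params <- function(net) {
  K <- net$n_neurons
  tibble::tibble(
    name = c(as.vector(rbind(paste0("w_in_", seq_len(K)), paste0("b_in_", seq_len(K)))),
             as.vector(vapply(c("S", "I", "R"), function(ch)
               c(paste0("w_out_", ch, "_", seq_len(K)), paste0("b_out_", ch)),
               character(K + 1)))),
    value = flatten_simple_net(net)
  )
}
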