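#' Configuration of the physics-informed network fit
#'
#' Defaults reproduce the reference protocol: a fully connected
#' 1-64-64-64-3 ReLU network trained by full-batch Adam at learning rate
#' 0.001 for 30,000 iterations, Glorot Uniform weight initialization,
#' epidemic rates initialized at zero and learned jointly with the
#' weights, and all nine loss weights (three per loss component) equal
#' to one.
#'
#' @param layers Hidden-layer widths (input is always the scalar time,
#'   output always the three compartments).
#' @param learning_rate Adam step size (> 0). Remaining Adam
#'   hyperparameters are the standard ones (0.9, 0.999, 1e-8).
#' @param iterations Number of full-batch gradient steps (>= 1); there is
#'   no early stopping.
#' @param trace_every Recording period of the training trace; iteration 0
#'   and the final iteration are always recorded.
#' @param init_seed Seed for the Glorot weight draw.
#' @param lambda_init Initial `(beta, sigma)`; both rates are unconstrained
#'   during training.
#' @param weights_ode,weights_ic,weights_data Per-compartment loss weights
#'   (S, I, R), all non-negative.
#' @param normalize Normalize the data to proportions before training
#'   (recommended: raw counts give poorly scaled losses under Glorot
#'   initialization). `beta` and `sigma` are unaffected.
#' @param freeze_lambda Keep `(beta, sigma)` fixed at `lambda_init`
#'   (forward-problem mode, useful for diagnostics).
#' @return A list of class `pinn_config`.
#' @export
pinn_config <- function(layers = c(64, 64, 64), learning_rate = 0.001,
                        iterations = 30000, trace_every = 100,
                        init_seed = 1L, lambda_init = c(0, 0),
                        weights_ode = c(1, 1, 1), weights_ic = c(1, 1, 1),
                        weights_data = c(1, 1, 1), normalize = TRUE,
                        freeze_lambda = FALSE) {
  stopifnot(length(layers) >= 1, all(layers >= 1))
  if (!is.finite(learning_rate) || learning_rate <= 0) {
    stop("learning_rate must be > 0", call. = FALSE)
  }
  if (iterations < 1) stop("iterations must be >= 1", call. = FALSE)
  weights <- c(weights_ode, weights_ic, weights_data)
  if (length(weights) != 9 || any(!is.finite(weights)) || any(weights < 0)) {
    stop("loss weights must be three non-negative values per component",
         call. = FALSE)
  }
  structure(list(layers = as.integer(layers), learning_rate = learning_rate,
                 iterations = as.integer(iterations),
                 trace_every = as.integer(trace_every),
                 init_seed = as.integer(init_seed),
                 lambda_init = as.numeric(lambda_init),
                 weights_ode = as.numeric(weights_ode),
                 weights_ic = as.numeric(weights_ic),
                 weights_data = as.numeric(weights_data),
                 normalize = isTRUE(normalize),
                 freeze_lambda = isTRUE(freeze_lambda)),
            class = "pinn_config")
}

#' Train the physics-informed network on SIR data
#'
#' Fits a dense ReLU network `u(t) = (S, I, R)` to an observed epidemic
#' time series by full-batch Adam on the composite loss
#' `L = L_ode + L_ic + L_data`, where `L_ode` penalizes the SIR
#' differential residuals of the network's own outputs (time derivatives
#' from the exact forward-mode tangent of the network, evaluated at the
#' observation days, which double as collocation points), `L_ic` the
#' initial-condition misfit, and `L_data` the data misfit. The epidemic
#' rates `(beta, sigma)` are appended to the learnable parameters and
#' take identical gradient steps — the inverse problem is solved jointly
#' with the trajectory reconstruction.
#'
#' Training is deterministic given `config$init_seed` (single-threaded
#' linear algebra): the only random element is the Glorot weight draw.
#'
#' @param data An [sir_trajectory()] (noisy or clean) on the observation
#'   grid; non-empty.
#' @param config A [pinn_config()].
#' @return An object of class `pinn_fit` with elements `theta` (trained
#'   weights), `lambda_hat` (named estimates of `beta`, `sigma`), `trace`
#'   (tibble of the learning process: iteration, `beta_hat`, `sigma_hat`,
#'   per-compartment ODE losses, `L_ic`, `L_data`, `total`), `config`,
#'   the (normalized) training data and the original population scale.
#'   Methods: `predict()`, [tidy()], [glance()], [autoplot()].
#' @examples
#' \donttest{
#' data <- sir_synthetic_data(seed = 1)
#' fit <- train_pinn(data, pinn_config(layers = c(16, 16), iterations = 2000))
#' tidy(fit)
#' }
#' @export
train_pinn <- function(data, config = pinn_config()) {
  stopifnot(inherits(config, "pinn_config"))
  if (nrow(data) == 0) stop("data must be non-empty", call. = FALSE)
  N_orig <- trajectory_N(data)
  train <- if (config$normalize) normalize_trajectory(data) else data
  ord <- order(train$t)
  tt <- train$t[ord]
  U <- rbind(train$S, train$I, train$R)[, ord, drop = FALSE]

  theta0 <- glorot_uniform_init(c(1, config$layers, 3), config$init_seed)
  res <- cpp_train_pinn(theta0$W, theta0$b, tt, U, config$lambda_init,
                        config$learning_rate, config$iterations,
                        config$trace_every, config$weights_ode,
                        config$weights_ic, config$weights_data,
                        config$freeze_lambda)
  trace <- pinn_trace_tibble(res$trace)
  if (isTRUE(res$diverged)) {
    rlang::abort("PINN training diverged (non-finite loss)",
                 class = "dinnr_training_failure", trace_so_far = trace)
  }
  structure(list(
    theta = list(W = res$W, b = lapply(res$b, as.numeric)),
    lambda_hat = c(beta = as.numeric(res$lambda)[1],
                   sigma = as.numeric(res$lambda)[2]),
    trace = trace,
    config = config,
    data = train,
    N = N_orig
  ), class = "pinn_fit")
}

pinn_trace_tibble <- function(m) {
  colnames(m) <- c("iteration", "beta_hat", "sigma_hat", "L_ode_S", "L_ode_I",
                   "L_ode_R", "L_ic", "L_data", "total")
  out <- tibble::as_tibble(m)
  out$iteration <- as.integer(out$iteration)
  out
}

#' SIR differential residuals of a network model
#'
#' Evaluates the three ODE residuals of the network outputs at the given
#' times, using the network's exact time derivative:
#' `r_S = dS/dt + beta*S*I/N`, `r_I = dI/dt - beta*S*I/N + sigma*I`,
#' `r_R = dR/dt - sigma*I`. By construction the three residuals sum to
#' `dS/dt + dI/dt + dR/dt` at every time (the rate terms cancel).
#'
#' @param model A `pinn_fit`, or a list with elements `theta` (dense
#'   parameters) and `lambda_hat` (`c(beta, sigma)`).
#' @param t Times at which to evaluate (days). Defaults to the training
#'   grid for a `pinn_fit`.
#' @param N Population scale the network outputs live on (1 for
#'   normalized training, the default).
#' @return A tibble with columns `t`, `res_S`, `res_I`, `res_R`.
#' @export
ode_residuals <- function(model, t = NULL, N = 1) {
  theta <- model$theta
  lambda <- model$lambda_hat
  if (is.null(t)) {
    if (is.null(model$data)) stop("supply evaluation times t", call. = FALSE)
    t <- model$data$t
  }
  fw <- dense_forward(theta, t)
  if (!all(is.finite(fw$u))) stop("non-finite network output", call. = FALSE)
  beta <- lambda[[1]]; sigma <- lambda[[2]]
  SI <- fw$u[, "S"] * fw$u[, "I"] / N
  tibble::tibble(
    t = t,
    res_S = fw$du[, "S"] + beta * SI,
    res_I = fw$du[, "I"] - beta * SI + sigma * fw$u[, "I"],
    res_R = fw$du[, "R"] - sigma * fw$u[, "I"]
  )
}

#' Composite PINN loss of a model on a dataset
#'
#' Pure-R evaluation of the training objective (see [train_pinn()]),
#' useful for inspection and testing: per-compartment ODE residual losses
#' (mean of squared residuals over the collocation days, weighted),
#' initial-condition loss and data loss, plus their total.
#'
#' @inheritParams ode_residuals
#' @param data An [sir_trajectory()] on the scale the model was trained on.
#' @param config A [pinn_config()] supplying the loss weights.
#' @return A list with `L_ode_S`, `L_ode_I`, `L_ode_R`, `L_ode`, `L_ic`,
#'   `L_data` and `total`.
#' @export
pinn_loss <- function(model, data, config = pinn_config()) {
  if (nrow(data) == 0) stop("data must be non-empty", call. = FALSE)
  ord <- order(data$t)
  tt <- data$t[ord]
  U <- cbind(data$S, data$I, data$R)[ord, , drop = FALSE]
  r <- ode_residuals(model, t = tt)
  w_ode <- config$weights_ode
  L_ode <- c(w_ode[1] * mean(r$res_S^2), w_ode[2] * mean(r$res_I^2),
             w_ode[3] * mean(r$res_R^2))
  Uhat <- eval_dense(model$theta, tt)
  E <- Uhat - U
  L_data <- sum(config$weights_data / nrow(U) * colSums(E^2))
  L_ic <- sum(config$weights_ic * E[1, ]^2)
  list(L_ode_S = L_ode[1], L_ode_I = L_ode[2], L_ode_R = L_ode[3],
       L_ode = sum(L_ode), L_ic = L_ic, L_data = L_data,
       total = sum(L_ode) + L_ic + L_data)
}

#' Relative error of a rate estimate
#'
#' `|estimate - truth| / |truth|`, the accuracy metric used throughout for
#' the recovered epidemic rates.
#'
#' @param estimate Estimated value.
#' @param truth True value; must be nonzero.
#' @return Dimensionless fraction.
#' @examples
#' relative_error(0.4971, 0.5)
#' @export
relative_error <- function(estimate, truth) {
  if (!is.finite(truth) || truth == 0) {
    stop("truth must be finite and nonzero", call. = FALSE)
  }
  abs(estimate - truth) / abs(truth)
}

#' @export
print.pinn_fit <- function(x, ...) {
  cat("Physics-informed network fit (SIR inverse problem)\n")
  cat(sprintf("  architecture: 1-%s-3 (ReLU), %d Adam iterations @ lr %g\n",
              paste(x$config$layers, collapse = "-"), x$config$iterations,
              x$config$learning_rate))
  cat(sprintf("  beta_hat = %.6f   sigma_hat = %.6f\n",
              x$lambda_hat[["beta"]], x$lambda_hat[["sigma"]]))
  fin <- x$trace[nrow(x$trace), ]
  cat(sprintf("  final loss: %.4e (ode %.2e + ic %.2e + data %.2e)\n",
              fin$total, fin$L_ode_S + fin$L_ode_I + fin$L_ode_R, fin$L_ic,
              fin$L_data))
  invisible(x)
}

#' @export
predict.pinn_fit <- function(object, t = object$data$t, scale = object$N, ...) {
  u <- eval_dense(object$theta, t)
  rescale <- if (object$config$normalize) scale else 1
  tibble::tibble(t = t, S = u[, "S"] * rescale, I = u[, "I"] * rescale,
                 R = u[, "R"] * rescale)
}

#' @export
tidy.pinn_fit <- function(x, beta_true = NULL, sigma_true = NULL, ...) {
  out <- tibble::tibble(term = c("beta", "sigma"),
                        estimate = as.numeric(x$lambda_hat))
  if (!is.null(beta_true) && !is.null(sigma_true)) {
    truth <- c(beta_true, sigma_true)
    out$true <- truth
    out$rel_error <- mapply(relative_error, out$estimate, truth)
  }
  out
}

#' @export
glance.pinn_fit <- function(x, ...) {
  fin <- x$trace[nrow(x$trace), ]
  tibble::tibble(iterations = x$config$iterations,
                 beta_hat = x$lambda_hat[["beta"]],
                 sigma_hat = x$lambda_hat[["sigma"]],
                 L_ode = fin$L_ode_S + fin$L_ode_I + fin$L_ode_R,
                 L_ic = fin$L_ic, L_data = fin$L_data, total = fin$total)
}

#' @export
autoplot.pinn_fit <- function(object, ...) {
  obs <- tidyr::pivot_longer(tibble::as_tibble(object$data), c("S", "I", "R"),
                             names_to = "compartment", values_to = "value")
  pred <- predict(object, scale = 1)
  pred <- tidyr::pivot_longer(pred, c("S", "I", "R"),
                              names_to = "compartment", values_to = "value")
  obs$compartment <- factor(obs$compartment, levels = c("S", "I", "R"))
  pred$compartment <- factor(pred$compartment, levels = c("S", "I", "R"))
  ggplot2::ggplot(mapping = ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_point(data = obs, size = 0.7, alpha = 0.6) +
    ggplot2::geom_line(data = pred, colour = "steelblue") +
    ggplot2::facet_wrap(~compartment, scales = "free_y") +
    ggplot2::labs(x = "time (days)", y = "proportion of population")
}
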