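#' Forward finite differences on a daily series
#'
#' The discrete derivative used by the spreadsheet-style simple DINN:
#' with a time step of one day, `d[j] = x[j+1] - x[j]` for
#' `j = 1..(T-1)`. The final day has no forward neighbour, so the result
#' has one fewer element than the input.
#'
#' @param series Numeric vector sampled on a unit-spaced grid, length >= 2.
#' @return Numeric vector of slopes (per day), length `length(series) - 1`.
#' @examples
#' fd_derivative((0:5)^2) # 2j + 1
#' @export
fd_derivative <- function(series) {
  if (length(series) < 2) {
    stop("series must have at least 2 points for a forward difference",
         call. = FALSE)
  }
  diff(series)
}

#' Composite loss of the simple finite-difference DINN
#'
#' Two terms, evaluated on normalized (proportion-scale) data sorted by
#' time:
#' \itemize{
#'   \item `mse_data`: mean over all days and compartments of the squared
#'     difference between network prediction and observation;
#'   \item `dinn_residual`: sum over the three compartments of the
#'     per-compartment means, over the interior days (all but the last),
#'     of the squared forward-difference SIR residuals
#'     \eqn{(\Delta S_j + \beta S_j I_j)^2}, \eqn{(\Delta I_j - \beta S_j
#'     I_j + \sigma I_j)^2}, \eqn{(\Delta R_j - \sigma I_j)^2},
#'     where the differences and states are by default the network's own
#'     predictions on the daily grid.
#' }
#' The total is `w_data * mse_data + w_ode * dinn_residual`.
#'
#' @param net A [simple_net()].
#' @param beta,sigma Candidate epidemic rates (1/day).
#' @param data A normalized [sir_trajectory()] (`N = 1`).
#' @param loss_weights Named vector `c(data = , ode = )`, non-negative and
#'   not both zero.
#' @param fd_on `"network"` (default): differences and residual states are
#'   taken on the network predictions; `"data"`: taken on the observations,
#'   for comparison.
#' @return A list with `mse_data`, `dinn_residual` and `total`.
#' @export
simple_loss <- function(net, beta, sigma, data,
                        loss_weights = c(data = 1, ode = 1),
                        fd_on = c("network", "data")) {
  fd_on <- match.arg(fd_on)
  check_loss_weights(loss_weights)
  if (nrow(data) == 0) stop("data must have at least one day", call. = FALSE)
  if (abs(trajectory_N(data) - 1) > 1e-12) {
    stop("simple_loss expects normalized data (N = 1); see normalize_trajectory()",
         call. = FALSE)
  }
  ord <- order(data$t)
  tt <- data$t[ord]
  U <- cbind(data$S, data$I, data$R)[ord, , drop = FALSE]
  p <- c(flatten_simple_net(net), beta, sigma)
  parts <- simple_loss_eval(p, net$n_neurons, tt, U,
                            w_data = loss_weights[["data"]],
                            w_ode = loss_weights[["ode"]],
                            fd_on = fd_on, want_grad = FALSE)
  parts[c("mse_data", "dinn_residual", "total")]
}

clamp <- function(x, box) pmin(pmax(x, box[1]), box[2])

check_loss_weights <- function(loss_weights) {
  if (!all(c("data", "ode") %in% names(loss_weights))) {
    stop("loss_weights must carry named entries 'data' and 'ode'", call. = FALSE)
  }
  if (any(loss_weights < 0) || sum(loss_weights) == 0) {
    stop("loss_weights must be non-negative and not both zero", call. = FALSE)
  }
  invisible(TRUE)
}

# Loss (and analytic gradient) in terms of the flat parameter vector
# p = c(flatten_simple_net(net), beta, sigma). Gradients of the ReLU mask
# are treated as zero, the usual subgradient convention.
simple_loss_eval <- function(p, K, tt, U, w_data, w_ode, fd_on, want_grad) {
  n_net <- 2 * K + 3 * (K + 1)
  beta <- p[n_net + 1]
  sigma <- p[n_net + 2]
  hidden <- matrix(p[seq_len(2 * K)], nrow = 2)
  w_in <- hidden[1, ]
  b_in <- hidden[2, ]
  output <- matrix(p[(2 * K + 1):n_net], nrow = K + 1)
  W_out <- t(output[seq_len(K), , drop = FALSE])   # 3 x K
  b_out <- output[K + 1, ]
  Tn <- length(tt)

  Z <- outer(tt, w_in) + matrix(b_in, Tn, K, byrow = TRUE)
  mask <- Z > 0
  H <- Z * mask
  P <- H %*% t(W_out) + matrix(b_out, Tn, 3, byrow = TRUE)

  E <- P - U
  mse <- mean(E^2)
  G <- 2 * w_data * E / length(E)

  gbeta <- 0; gsigma <- 0; res <- 0
  if (Tn >= 2) {
    X <- if (fd_on == "network") P else U
    idx <- seq_len(Tn - 1)
    dX <- X[idx + 1, , drop = FALSE] - X[idx, , drop = FALSE]
    S_ <- X[idx, 1]; I_ <- X[idx, 2]
    rS <- dX[, 1] + beta * S_ * I_
    rI <- dX[, 2] - beta * S_ * I_ + sigma * I_
    rR <- dX[, 3] - sigma * I_
    res <- mean(rS^2) + mean(rI^2) + mean(rR^2)
    A <- 2 * w_ode / (Tn - 1)
    BS <- A * rS; BI <- A * rI; BR <- A * rR
    gbeta <- sum((BS - BI) * S_ * I_)
    gsigma <- sum((BI - BR) * I_)
    if (fd_on == "network") {
      G[idx, 1] <- G[idx, 1] + BS * (beta * I_ - 1) - BI * beta * I_
      G[idx + 1, 1] <- G[idx + 1, 1] + BS
      G[idx, 2] <- G[idx, 2] + BS * beta * S_ + BI * (sigma - beta * S_ - 1) - BR * sigma
      G[idx + 1, 2] <- G[idx + 1, 2] + BI
      G[idx, 3] <- G[idx, 3] - BR
      G[idx + 1, 3] <- G[idx + 1, 3] + BR
    }
  }

  total <- w_data * mse + w_ode * res
  out <- list(mse_data = mse, dinn_residual = res, total = total)
  if (!want_grad) return(out)

  g_b_out <- colSums(G)
  g_W_out <- t(G) %*% H                       # 3 x K
  M <- (G %*% W_out) * mask                   # Tn x K
  g_w_in <- colSums(M * tt)
  g_b_in <- colSums(M)
  out$grad <- c(as.numeric(rbind(g_w_in, g_b_in)),
                as.numeric(t(cbind(g_W_out, g_b_out))),
                gbeta, gsigma)
  out
}

#' Fit the simple finite-difference DINN by multistart optimization
#'
#' Jointly estimates the network parameters and the epidemic rates
#' `(beta, sigma)` of the SIR model by minimizing [simple_loss()] over
#' `n_restarts` random starting points inside the parameter box — the
#' generic multistart nonlinear-solver strategy of the spreadsheet
#' method. Data are normalized to proportions internally; `beta` and
#' `sigma` are invariant under that rescaling. The hidden layer is fed
#' time rescaled to `[0, 1]` during optimization so that random starts
#' place ReLU kinks throughout the observation window rather than
#' clustering them near `t = 0` (the returned network is expressed back
#' in day units).
#'
#' Each restart draws the hidden-layer affine parameters uniformly within
#' the box; the output layer of the start is then completed by a
#' ridge-stabilized linear least-squares readout of the data on the drawn
#' ReLU basis (the readout is linear in those parameters, so there is no
#' reason to guess it), and the rates start at their finite-difference
#' regression estimates from the data. The local minimizer then moves
#' every parameter jointly. Purely uniform starts are also available
#' (`start = "uniform"`) but frequently stall in basins where the network
#' is effectively linear over the window.
#'
#' The objective is a sum of squares (data misfit plus finite-difference
#' residuals), so the default local optimizer is bounded
#' Levenberg-Marquardt ([minpack.lm::nls.lm()]); `"l-bfgs-b"` selects a
#' bounded quasi-Newton minimizer instead.
#'
#' @param data An [sir_trajectory()] with at least 2 days on a unit grid.
#' @param n_neurons Hidden width (1 to 5 in the reference study).
#' @param n_restarts Number of random restarts (>= 1).
#' @param loss_weights As in [simple_loss()].
#' @param bounds List with elements `weight` (box for every network weight
#'   and bias, on the normalized data and time scale), `beta` and `sigma`
#'   (boxes for the rates).
#' @param tolerance Optimizer convergence tolerance (`ftol`/`ptol` for
#'   Levenberg-Marquardt, scaled into `factr` for `L-BFGS-B`).
#' @param max_iter Iteration cap per restart.
#' @param seed Seed for the restart draws; restarts are drawn sequentially,
#'   so a longer run extends a shorter one (the best loss is non-increasing
#'   in `n_restarts`).
#' @param fd_on As in [simple_loss()].
#' @param optimizer Local minimizer: `"levenberg-marquardt"` (default) or
#'   `"l-bfgs-b"`.
#' @param start Restart construction: `"readout"` (default; random hidden
#'   layer completed by a least-squares output readout and
#'   finite-difference rate estimates) or `"uniform"` (every parameter
#'   uniform in its box).
#' @return An object of class `simple_dinn_fit` with the best network,
#'   `beta_hat`, `sigma_hat`, a loss breakdown and per-restart losses.
#'   Methods: [tidy()], [glance()], `predict()`, [autoplot()].
#' @examples
#' \donttest{
#' data <- sir_synthetic_data(seed = 1)
#' fit <- fit_simple_dinn(data, n_neurons = 5, n_restarts = 5, seed = 1)
#' tidy(fit)
#' }
#' @export
fit_simple_dinn <- function(data, n_neurons = 5, n_restarts = 20,
                            loss_weights = c(data = 1, ode = 1),
                            bounds = list(weight = c(-5, 5), beta = c(0, 2),
                                          sigma = c(0, 1)),
                            tolerance = 1e-10, max_iter = 10000, seed = 1,
                            fd_on = c("network", "data"),
                            optimizer = c("levenberg-marquardt", "l-bfgs-b"),
                            start = c("readout", "uniform")) {
  fd_on <- match.arg(fd_on)
  optimizer <- match.arg(optimizer)
  start <- match.arg(start)
  check_loss_weights(loss_weights)
  if (nrow(data) < 2) stop("data must have at least 2 days", call. = FALSE)
  if (n_restarts < 1) stop("n_restarts must be >= 1", call. = FALSE)
  norm <- normalize_trajectory(data)
  ord <- order(norm$t)
  t_day <- norm$t[ord]
  t_range <- t_day[length(t_day)] - t_day[1]
  tt <- (t_day - t_day[1]) / t_range   # unit-interval time for the optimizer
  U <- cbind(norm$S, norm$I, norm$R)[ord, , drop = FALSE]

  K <- as.integer(n_neurons)
  n_net <- 2 * K + 3 * (K + 1)
  npar <- n_net + 2
  lower <- c(rep(bounds$weight[1], n_net), bounds$beta[1], bounds$sigma[1])
  upper <- c(rep(bounds$weight[2], n_net), bounds$beta[2], bounds$sigma[2])

  w_data <- loss_weights[["data"]]
  w_ode <- loss_weights[["ode"]]
  fn <- function(p) simple_loss_eval(p, K, tt, U, w_data, w_ode, fd_on, FALSE)$total
  gr <- function(p) simple_loss_eval(p, K, tt, U, w_data, w_ode, fd_on, TRUE)$grad
  res_fn <- function(p) simple_loss_resid(p, K, tt, U, w_data, w_ode, fd_on)

  # rate starts shared by every readout restart: finite-difference
  # regression of the SIR right-hand side on the (normalized) data
  fd_rate_start <- function() {
    Tn <- length(tt)
    idx <- seq_len(Tn - 1)
    dU <- U[idx + 1, , drop = FALSE] - U[idx, , drop = FALSE]
    S_ <- U[idx, 1]; I_ <- U[idx, 2]
    sig0 <- sum(dU[, 3] * I_) / sum(I_^2)
    bet0 <- -sum(dU[, 1] * S_ * I_) / sum((S_ * I_)^2)
    c(clamp(bet0, bounds$beta), clamp(sig0, bounds$sigma))
  }
  rate0 <- fd_rate_start()

  make_start <- function() {
    if (start == "uniform") {
      return(lower + stats::runif(npar) * (upper - lower))
    }
    w0 <- stats::runif(K, bounds$weight[1], bounds$weight[2])
    b0 <- stats::runif(K, bounds$weight[1], bounds$weight[2])
    H <- relu(outer(tt, w0) + matrix(b0, length(tt), K, byrow = TRUE))
    X <- cbind(H, 1)
    cf <- solve(crossprod(X) + 1e-8 * diag(K + 1), crossprod(X, U))
    cf <- clamp(cf, bounds$weight)
    c(as.numeric(rbind(w0, b0)), as.numeric(cf), rate0)
  }
  starts <- with_local_seed(seed, {
    vapply(seq_len(n_restarts), function(r) make_start(), numeric(npar))
  })
  starts <- matrix(starts, nrow = npar)

  pars <- vector("list", n_restarts)
  losses <- rep(NA_real_, n_restarts)
  msgs <- character(n_restarts)
  for (r in seq_len(n_restarts)) {
    sol <- tryCatch({
      if (optimizer == "levenberg-marquardt") {
        o <- minpack.lm::nls.lm(starts[, r], lower = lower, upper = upper,
                                fn = res_fn,
                                control = minpack.lm::nls.lm.control(
                                  maxiter = min(max_iter, 1024),
                                  ftol = tolerance, ptol = tolerance))
        o$par
      } else {
        o <- stats::optim(starts[, r], fn, gr, method = "L-BFGS-B",
                          lower = lower, upper = upper,
                          control = list(maxit = max_iter,
                                         factr = tolerance / .Machine$double.eps))
        o$par
      }
    }, error = function(e) e)
    if (inherits(sol, "error")) {
      msgs[r] <- conditionMessage(sol)
    } else {
      pars[[r]] <- sol
      losses[r] <- fn(sol)
    }
  }
  if (!any(is.finite(losses))) {
    stop("all ", n_restarts, " restarts failed: ",
         paste(unique(msgs[nzchar(msgs)]), collapse = "; "), call. = FALSE)
  }
  best <- which.min(losses)
  p <- pars[[best]]
  parts <- simple_loss_eval(p, K, tt, U, w_data, w_ode, fd_on, FALSE)
  # re-express the hidden layer in day units: z = w*ts + b with
  # ts = (t - t0)/range  =>  w_day = w/range, b_day = b - w*t0/range
  net <- unflatten_simple_net(p[seq_len(n_net)], K)
  net <- simple_net(K, w_in = net$w_in / t_range,
                    b_in = net$b_in - net$w_in * t_day[1] / t_range,
                    W_out = net$W_out, b_out = net$b_out)
  structure(list(
    net = net,
    beta_hat = p[n_net + 1],
    sigma_hat = p[n_net + 2],
    loss = parts,
    per_restart_losses = losses,
    best_restart = best,
    n_neurons = K,
    loss_weights = c(data = w_data, ode = w_ode),
    fd_on = fd_on,
    optimizer = optimizer,
    seed = seed,
    data = norm
  ), class = "simple_dinn_fit")
}

# Stacked residual vector whose sum of squares equals the weighted total
# loss: data misfit entries scaled by sqrt(w_data / (3T)) and
# finite-difference residual entries by sqrt(w_ode / (3(T-1))).
simple_loss_resid <- function(p, K, tt, U, w_data, w_ode, fd_on) {
  n_net <- 2 * K + 3 * (K + 1)
  beta <- p[n_net + 1]
  sigma <- p[n_net + 2]
  net <- unflatten_simple_net(p[seq_len(n_net)], K)
  P <- eval_simple_net(net, tt)
  Tn <- length(tt)
  E <- (P - U) * sqrt(w_data / (3 * Tn))
  X <- if (fd_on == "network") P else U
  idx <- seq_len(Tn - 1)
  dX <- X[idx + 1, , drop = FALSE] - X[idx, , drop = FALSE]
  S_ <- X[idx, 1]; I_ <- X[idx, 2]
  r <- cbind(dX[, 1] + beta * S_ * I_,
             dX[, 2] - beta * S_ * I_ + sigma * I_,
             dX[, 3] - sigma * I_) * sqrt(w_ode / (Tn - 1))
  c(as.numeric(E), as.numeric(r))
}

#' @export
print.simple_dinn_fit <- function(x, ...) {
  cat("Simple finite-difference DINN fit\n")
  cat(sprintf("  hidden neurons: %d   restarts: %d (best: #%d)\n",
              x$n_neurons, length(x$per_restart_losses), x$best_restart))
  cat(sprintf("  beta_hat = %.6f   sigma_hat = %.6f\n", x$beta_hat, x$sigma_hat))
  cat(sprintf("  loss: data MSE %.3e + ODE residual %.3e = %.3e\n",
              x$loss$mse_data, x$loss$dinn_residual, x$loss$total))
  invisible(x)
}

#' @export
predict.simple_dinn_fit <- function(object, t = object$data$t, ...) {
  out <- tibble::as_tibble(eval_simple_net(object$net, t))
  out$t <- t
  out[, c("t", "S", "I", "R")]
}

#' @export
tidy.simple_dinn_fit <- function(x, beta_true = NULL, sigma_true = NULL, ...) {
  out <- tibble::tibble(term = c("beta", "sigma"),
                        estimate = c(x$beta_hat, x$sigma_hat))
  if (!is.null(beta_true) && !is.null(sigma_true)) {
    truth <- c(beta_true, sigma_true)
    out$true <- truth
    out$rel_error <- mapply(relative_error, out$estimate, truth)
  }
  out
}

#' @export
glance.simple_dinn_fit <- function(x, ...) {
  tibble::tibble(n_neurons = x$n_neurons,
                 n_restarts = length(x$per_restart_losses),
                 beta_hat = x$beta_hat, sigma_hat = x$sigma_hat,
                 mse_data = x$loss$mse_data,
                 dinn_residual = x$loss$dinn_residual,
                 total_loss = x$loss$total)
}

#' @export
autoplot.simple_dinn_fit <- function(object, ...) {
  obs <- tidyr::pivot_longer(tibble::as_tibble(object$data), c("S", "I", "R"),
                             names_to = "compartment", values_to = "value")
  pred <- tidyr::pivot_longer(predict(object), c("S", "I", "R"),
                              names_to = "compartment", values_to = "value")
  obs$compartment <- factor(obs$compartment, levels = c("S", "I", "R"))
  pred$compartment <- factor(pred$compartment, levels = c("S", "I", "R"))
  ggplot2::ggplot(mapping = ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_point(data = obs, size = 0.7, alpha = 0.6) +
    ggplot2::geom_line(data = pred, colour = "firebrick") +
    ggplot2::facet_wrap(~compartment, scales = "free_y") +
    ggplot2::labs(x = "time (days)", y = "proportion of population")
}

#' Relative parameter error as a function of network width
#'
#' Runs [fit_simple_dinn()] once per requested hidden width on shared data
#' and a shared seed schedule, and reports the relative errors of the rate
#' estimates against known true values. A failed fit is recorded in its
#' row (message in `error`, `NA` estimates); the sweep continues.
#'
#' @param data An [sir_trajectory()].
#' @param widths Integer vector of hidden widths (subset of 1..5 typically).
#' @param beta_true,sigma_true True rates used for the relative errors.
#' @param ... Further arguments passed to [fit_simple_dinn()].
#' @return A tibble sorted by width with columns `n_neurons`, `beta_hat`,
#'   `sigma_hat`, `rel_err_beta`, `rel_err_sigma`, `total_loss`, `error`.
#' @export
error_vs_neurons <- function(data, widths = 1:5, beta_true = 0.5,
                             sigma_true = 1 / 14, ...) {
  widths <- sort(unique(as.integer(widths)))
  rows <- purrr::map(widths, function(K) {
    fit <- tryCatch(fit_simple_dinn(data, n_neurons = K, ...),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      tibble::tibble(n_neurons = K, beta_hat = NA_real_, sigma_hat = NA_real_,
                     rel_err_beta = NA_real_, rel_err_sigma = NA_real_,
                     total_loss = NA_real_, error = conditionMessage(fit))
    } else {
      tibble::tibble(n_neurons = K, beta_hat = fit$beta_hat,
                     sigma_hat = fit$sigma_hat,
                     rel_err_beta = relative_error(fit$beta_hat, beta_true),
                     rel_err_sigma = relative_error(fit$sigma_hat, sigma_true),
                     total_loss = fit$loss$total, error = NA_character_)
    }
  })
  dplyr::bind_rows(rows)
}
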