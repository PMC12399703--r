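test_that("forward differences are exact on polynomials and reject short input", {
  expect_equal(fd_derivative(rep(7, 6)), rep(0, 5))
  expect_equal(fd_derivative(3 * (0:9)), rep(3, 9))
  expect_equal(fd_derivative((0:5)^2), 2 * (0:4) + 1)
  expect_error(fd_derivative(1), "at least 2")
})

test_that("simple_loss vanishes on an exact fit of exact-ODE data", {
  traj <- constant_disease_free_traj(days = 8, S = 0.9, R = 0.1)
  net <- simple_net(2, w_in = c(0, 0), b_in = c(0, 0),
                    W_out = matrix(0, 3, 2), b_out = c(0.9, 0, 0.1))
  for (rates in list(c(0.5, 1 / 14), c(2, 1), c(0, 0))) {
    parts <- simple_loss(net, rates[1], rates[2], traj)
    expect_equal(parts$mse_data, 0)
    expect_equal(parts$dinn_residual, 0)
    expect_equal(parts$total, 0)
  }
})

test_that("simple_loss single-day hand value and weight linearity hold", {
  traj <- sir_trajectory(t = 0, S = 0.9, I = 0, R = 0.1, N = 1)
  # prediction - observation = 2 in the S channel only
  net <- simple_net(1, 0, 0, matrix(0, 3, 1), b_out = c(2.9, 0, 0.1))
  parts <- simple_loss(net, 0.5, 1 / 14, traj)
  # the squared error contributes 4 to the sum; the data MSE averages the
  # 3 per-compartment entries of the single day
  expect_equal(parts$mse_data, 4 / 3)
  expect_equal(parts$dinn_residual, 0)
  expect_equal(parts$total, 4 / 3)

  # doubling w_ode doubles only the residual contribution
  d <- reference_noisy_data()
  norm <- normalize_trajectory(d)
  net <- unflatten_simple_net(seq(-0.5, 0.5, length.out = 18), 3)
  l1 <- simple_loss(net, 0.4, 0.1, norm, loss_weights = c(data = 1, ode = 1))
  l2 <- simple_loss(net, 0.4, 0.1, norm, loss_weights = c(data = 1, ode = 2))
  expect_equal(l2$mse_data, l1$mse_data)
  expect_equal(l2$dinn_residual, l1$dinn_residual)
  expect_equal(l2$total - l1$total, l1$dinn_residual)

  # with w_ode = 0 the loss is plain least squares, independent of the rates
  l3 <- simple_loss(net, 0.4, 0.1, norm, loss_weights = c(data = 1, ode = 0))
  l4 <- simple_loss(net, 1.7, 0.9, norm, loss_weights = c(data = 1, ode = 0))
  expect_equal(l3$total, l3$mse_data)
  expect_equal(l3$total, l4$total)

  expect_error(simple_loss(net, 0.4, 0.1, norm[0, ]), "at least one day")
  expect_error(simple_loss(net, 0.4, 0.1, d), "normalized")
})

test_that("simple_loss is invariant under permutation of the day order", {
  norm <- normalize_trajectory(reference_noisy_data())
  net <- unflatten_simple_net(seq(-1, 1, length.out = 18), 3)
  ref <- simple_loss(net, 0.5, 1 / 14, norm)
  set.seed(9)
  for (i in 1:5) {
    # out-of-order rows, same (t, S, I, R) records
    shuffled <- norm[sample(nrow(norm)), ]
    attr(shuffled, "N") <- 1
    expect_equal(simple_loss(net, 0.5, 1 / 14, shuffled), ref)
  }
})

test_that("the analytic gradient of the training objective matches finite differences", {
  d <- normalize_trajectory(reference_noisy_data())
  tt <- d$t / max(d$t)
  U <- cbind(d$S, d$I, d$R)
  for (K in c(1, 3)) {
    set.seed(K)
    npar <- 2 * K + 3 * (K + 1) + 2
    p <- c(runif(npar - 2, -0.8, 0.8), 0.4, 0.1)
    for (fd_on in c("network", "data")) {
      f <- function(p) simple_loss_eval(p, K, tt, U, 1, 1.3, fd_on, FALSE)$total
      g <- simple_loss_eval(p, K, tt, U, 1, 1.3, fd_on, TRUE)$grad
      gn <- vapply(seq_len(npar), function(i) {
        h <- 1e-6
        pp <- p; pp[i] <- p[i] + h
        pm <- p; pm[i] <- p[i] - h
        (f(pp) - f(pm)) / (2 * h)
      }, numeric(1))
      expect_equal(g, gn, tolerance = 1e-6)
    }
  }
})

test_that("fit_simple_dinn is deterministic, bounded and improves with restarts", {
  d <- reference_noisy_data()
  f1 <- fit_simple_dinn(d, n_neurons = 2, n_restarts = 3, seed = 7)
  f2 <- fit_simple_dinn(d, n_neurons = 2, n_restarts = 3, seed = 7)
  expect_equal(f1$beta_hat, f2$beta_hat)
  expect_equal(f1$per_restart_losses, f2$per_restart_losses)

  # restart schedule is a prefix: more restarts can only improve the optimum
  f6 <- fit_simple_dinn(d, n_neurons = 2, n_restarts = 6, seed = 7)
  expect_equal(f6$per_restart_losses[1:3], f1$per_restart_losses)
  expect_lte(min(f6$per_restart_losses), min(f1$per_restart_losses))

  # the winner attains the minimum and respects the boxes
  expect_equal(f6$loss$total, min(f6$per_restart_losses))
  expect_gte(f6$beta_hat, 0)
  expect_lte(f6$beta_hat, 2)
  expect_gte(f6$sigma_hat, 0)
  expect_lte(f6$sigma_hat, 1)

  # loss breakdown identity
  expect_equal(f6$loss$total, f6$loss$mse_data + f6$loss$dinn_residual)

  expect_error(fit_simple_dinn(d[0, ], n_neurons = 2), "at least 2 days")
  expect_error(fit_simple_dinn(d, n_neurons = 2, n_restarts = 0), "n_restarts")
})

test_that("the returned day-unit network reproduces the internal optimum", {
  d <- reference_noisy_data()
  fit <- fit_simple_dinn(d, n_neurons = 3, n_restarts = 5, seed = 2)
  parts <- simple_loss(fit$net, fit$beta_hat, fit$sigma_hat,
                       normalize_trajectory(d))
  expect_equal(parts$total, fit$loss$total, tolerance = 1e-10)

  pred <- predict(fit)
  expect_named(pred, c("t", "S", "I", "R"))
  expect_equal(nrow(pred), 60)

  td <- tidy(fit, beta_true = 0.5, sigma_true = 1 / 14)
  expect_equal(td$term, c("beta", "sigma"))
  expect_equal(td$rel_error[1], abs(fit$beta_hat - 0.5) / 0.5)
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})

test_that("error_vs_neurons sweeps widths, shares data, and survives per-row failure", {
  d <- reference_noisy_data()
  tab <- error_vs_neurons(d, widths = c(2, 1), seed = 3, n_restarts = 4)
  expect_equal(tab$n_neurons, c(1, 2))   # sorted by width
  expect_true(all(is.na(tab$error)))
  expect_equal(tab$rel_err_beta, abs(tab$beta_hat - 0.5) / 0.5)

  single <- error_vs_neurons(d, widths = 1, seed = 3, n_restarts = 2)
  expect_equal(nrow(single), 1)

  # degenerate data: every row records its error, the sweep does not abort
  bad <- error_vs_neurons(d[1, ], widths = 1:3, n_restarts = 2)
  expect_equal(nrow(bad), 3)
  expect_true(all(!is.na(bad$error)))
  expect_true(all(is.na(bad$beta_hat)))
})
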