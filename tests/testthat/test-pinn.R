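test_that("pinn_config validates its fields and carries protocol defaults", {
  cfg <- pinn_config()
  expect_equal(cfg$layers, c(64L, 64L, 64L))
  expect_equal(cfg$learning_rate, 0.001)
  expect_equal(cfg$iterations, 30000L)
  expect_equal(cfg$lambda_init, c(0, 0))
  expect_equal(cfg$weights_ode, c(1, 1, 1))
  expect_error(pinn_config(learning_rate = 0), "learning_rate")
  expect_error(pinn_config(iterations = 0), "iterations")
  expect_error(pinn_config(weights_ode = c(-1, 1, 1)), "non-negative")
})

test_that("ODE residuals vanish for constants with zero rates and sum to the derivative total", {
  # constant outputs solve the system when both rates are zero
  model <- list(theta = constant_output_theta(), lambda_hat = c(beta = 0, sigma = 0))
  r <- ode_residuals(model, t = 0:9)
  expect_true(all(abs(r$res_S) < 1e-14))
  expect_true(all(abs(r$res_I) < 1e-14))
  expect_true(all(abs(r$res_R) < 1e-14))

  # ... and for any rates, because I(t) = 0 in this model
  model$lambda_hat <- c(beta = 1.2, sigma = 0.3)
  r <- ode_residuals(model, t = 0:9)
  expect_true(all(abs(as.matrix(r[, -1])) < 1e-14))

  # the rate terms cancel in the sum: residuals add up to dS+dI+dR
  th <- glorot_uniform_init(c(1, 16, 16, 3), seed = 4)
  model <- list(theta = th, lambda_hat = c(beta = 0.7, sigma = 0.2))
  set.seed(21)
  tq <- runif(10, 0, 59)
  r <- ode_residuals(model, t = tq)
  du <- dense_time_derivative(th, tq)
  expect_equal(r$res_S + r$res_I + r$res_R, rowSums(du), tolerance = 1e-12)
})

test_that("pinn_loss composes its non-negative components and matches hand values", {
  norm <- normalize_trajectory(reference_noisy_data())
  th <- glorot_uniform_init(c(1, 8, 3), seed = 1)
  model <- list(theta = th, lambda_hat = c(beta = 0.3, sigma = 0.1))

  l <- pinn_loss(model, norm)
  comps <- c(l$L_ode_S, l$L_ode_I, l$L_ode_R, l$L_ic, l$L_data)
  expect_true(all(comps >= 0))
  expect_equal(l$total, sum(comps))
  expect_equal(l$L_ode, l$L_ode_S + l$L_ode_I + l$L_ode_R)

  # all weights zero -> zero loss
  cfg0 <- pinn_config(weights_ode = c(0, 0, 0), weights_ic = c(0, 0, 0),
                      weights_data = c(0, 0, 0))
  expect_equal(pinn_loss(model, norm, cfg0)$total, 0)

  # perfect constant model on constant disease-free data -> zero loss
  traj <- constant_disease_free_traj(days = 6)
  perfect <- list(theta = constant_output_theta(out = c(0.9, 0, 0.1)),
                  lambda_hat = c(beta = 0.5, sigma = 1 / 14))
  expect_lt(pinn_loss(perfect, traj)$total, 1e-20)

  # single day, single compartment, error 2, N_data = 1: L_data contributes 4
  one <- sir_trajectory(t = 0, S = 0.9, I = 0, R = 0.1, N = 1)
  off <- list(theta = constant_output_theta(out = c(2.9, 0, 0.1)),
              lambda_hat = c(beta = 0, sigma = 0))
  l1 <- pinn_loss(off, one)
  expect_equal(l1$L_data, 4)
  expect_equal(l1$L_ic, 4)

  expect_error(pinn_loss(model, norm[0, ]), "non-empty")
})

test_that("relative_error is the absolute fractional deviation", {
  expect_equal(relative_error(0.4971, 0.5), 0.0058)
  expect_equal(relative_error(0.607, 0.5), 0.214)
  expect_equal(relative_error(3.7, 3.7), 0)
  expect_equal(relative_error(-0.1, 0.1), 2)
  expect_error(relative_error(1, 0), "nonzero")
})

test_that("training starts at lambda = 0, records a full trace, and reduces the loss", {
  d <- reference_noisy_data()
  fit <- train_pinn(d, tiny_pinn_config())
  tr <- fit$trace

  expect_equal(tr$iteration[1], 0L)
  expect_equal(tr$beta_hat[1], 0)
  expect_equal(tr$sigma_hat[1], 0)
  expect_equal(tr$iteration[nrow(tr)], 300L)
  expect_equal(diff(tr$iteration[1:6]), rep(50L, 5))

  expect_lt(tr$total[nrow(tr)], tr$total[1])
  expect_true(all(tr$total >= 0))
  expect_equal(tr$total,
               tr$L_ode_S + tr$L_ode_I + tr$L_ode_R + tr$L_ic + tr$L_data,
               tolerance = 1e-12)

  # the R-side loss of the trained model reproduces the final C++ record
  l <- pinn_loss(fit, fit$data, fit$config)
  expect_equal(l$total, tr$total[nrow(tr)], tolerance = 1e-10)

  # predictions rescale to the population
  pred <- predict(fit)
  expect_equal(nrow(pred), 60)
  expect_true(all(is.finite(as.matrix(pred))))

  gl <- glance(fit)
  expect_equal(gl$beta_hat, fit$lambda_hat[["beta"]])
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
  expect_error(train_pinn(d[0, ], tiny_pinn_config()), "non-empty")
})

test_that("training is deterministic given the initialization seed", {
  d <- reference_noisy_data()
  f1 <- train_pinn(d, tiny_pinn_config())
  f2 <- train_pinn(d, tiny_pinn_config())
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$lambda_hat, f2$lambda_hat)
  f3 <- train_pinn(d, tiny_pinn_config(init_seed = 2))
  expect_false(isTRUE(all.equal(f3$lambda_hat, f1$lambda_hat)))
})

test_that("with frozen true rates on clean data the fit loss collapses", {
  clean <- reference_clean_data()
  cfg <- pinn_config(layers = c(32, 32), iterations = 3000, trace_every = 500,
                     init_seed = 1, lambda_init = c(0.5, 1 / 14),
                     freeze_lambda = TRUE)
  fit <- train_pinn(clean, cfg)
  tr <- fit$trace
  expect_equal(tr$beta_hat, rep(0.5, nrow(tr)))
  fit0 <- tr$L_ode_S[1] + tr$L_ode_I[1] + tr$L_ode_R[1] + tr$L_data[1]
  fitT <- tr$L_ode_S[nrow(tr)] + tr$L_ode_I[nrow(tr)] + tr$L_ode_R[nrow(tr)] +
    tr$L_data[nrow(tr)]
  expect_lt(fitT, fit0 / 10)
})

test_that("a non-finite loss fails with a trace-carrying training error", {
  d <- reference_noisy_data()
  d$I[5] <- Inf  # corrupt observation makes the loss non-finite
  err <- tryCatch(train_pinn(d, tiny_pinn_config()), error = function(e) e)
  expect_s3_class(err, "dinnr_training_failure")
  expect_true(!is.null(err$trace_so_far))
})

test_that("measurement noise degrades asymptotic rate recovery", {
  # At the default 1% noise the training-error floor (~1%) masks the noise
  # effect, so the contrast uses a resolvable 5% level: clean-data errors
  # must be clearly smaller, and small in absolute terms.
  clean <- reference_clean_data()
  err_of <- function(data, s) {
    fit <- train_pinn(data, pinn_config(init_seed = s))
    max(relative_error(fit$lambda_hat[["beta"]], 0.5),
        relative_error(fit$lambda_hat[["sigma"]], 1 / 14))
  }
  seeds <- 1:5
  e_clean <- mean(vapply(seeds, function(s) err_of(clean, s), numeric(1)))
  e_noisy <- mean(vapply(seeds, function(s)
    err_of(sir_synthetic_data(seed = s, noise = 0.05), s), numeric(1)))
  expect_lt(e_clean, e_noisy)
  expect_lt(e_clean, 0.02)
})
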