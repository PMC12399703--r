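# Shared fixtures, built in code.

# Reference study protocol: beta = 0.5, sigma = 1/14, N = 1000, S0 = 999,
# 60 days, 1% noise. Generated once per test run.
reference_noisy_data <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- sir_synthetic_data(seed = 1)
    cache
  }
})

reference_clean_data <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- sir_synthetic_data(seed = 1, noise = 0)
    cache
  }
})

# A trajectory that is constant in time with no infections: it solves the
# SIR system (and its forward-Euler discretization) exactly for any rates,
# and a zero-weight network reproduces it exactly.
constant_disease_free_traj <- function(days = 10, S = 0.9, R = 0.1) {
  sir_trajectory(t = seq_len(days) - 1, S = rep(S, days), I = rep(0, days),
                 R = rep(R, days), N = S + R)
}

# Small dense parameter set whose outputs are constant in t (zero weights).
constant_output_theta <- function(out = c(0.9, 0, 0.1), hidden = c(4, 4)) {
  theta <- glorot_uniform_init(c(1, hidden, 3), seed = 1)
  for (l in seq_along(theta$W)) theta$W[[l]][] <- 0
  theta$b[[length(theta$b)]] <- out
  theta
}

# Fast PINN configuration for structural tests (not for accuracy).
tiny_pinn_config <- function(init_seed = 1, ...) {
  pinn_config(layers = c(8, 8), iterations = 300, trace_every = 50,
              init_seed = init_seed, ...)
}
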