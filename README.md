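# dinnr — disease-informed neural networks for the SIR inverse problem

`dinnr` estimates the transmission rate β and recovery rate σ of the
Kermack–McKendrick SIR epidemic model *directly from a noisy time series of
compartment counts*, using physics-informed neural networks (PINNs). It is
aimed at epidemiological modellers and at anyone teaching or studying how
neural networks can be constrained by mechanistic models: the same inverse
problem is solved twice, once with a deliberately minimal one-hidden-layer
network trained by generic nonlinear optimization (the "simple DINN", the
kind of model that fits in a spreadsheet), and once with a multilayer
network trained by gradient descent with exact autodifferentiated time
derivatives.

## The model and the estimator

The SIR model partitions a closed population of size N into susceptible,
infectious and recovered compartments:

    dS/dt = −β S I / N
    dI/dt =  β S I / N − σ I
    dR/dt =  σ I,          S + I + R = N.

Given observations u^j = (S, I, R) on days t^j, a network û(t; θ) with one
input (time) and three outputs is trained to minimize

    L(θ, β, σ) = L_ode + L_ic + L_data,

where `L_data` is the misfit between û and the observations, `L_ic` the
misfit at t = 0, and `L_ode` the mean squared *differential residuals* of
the SIR equations evaluated on the network's own outputs, e.g.
r_S = dŜ/dt + β Ŝ Î / N. The decisive trick is that β and σ are appended
to the learnable parameters: minimizing L recovers the epidemic rates
jointly with the trajectory. Accuracy is reported as the relative error
|estimate − truth| / |truth|.

Two implementations of this idea are provided:

* **`fit_simple_dinn()`** — one hidden ReLU layer (1–5 neurons),
  derivatives by forward finite differences on the daily grid, trained by
  multistart bounded Levenberg–Marquardt over weights, biases, β and σ.
* **`train_pinn()`** — a 3×64 ReLU network with exact time derivatives
  (forward-mode tangent through the activation pattern), trained by
  full-batch Adam (learning rate 0.001, 30,000 iterations, Glorot Uniform
  initialization, β and σ initialized at 0); the training loop is compiled
  (RcppArmadillo), so a full run takes seconds on one CPU.

`sir_synthetic_data()` generates the reference study conditions: RK4
integration of the SIR model with β = 0.5, σ = 1/14, N = 1000,
(S₀, I₀, R₀) = (999, 1, 0), 60 daily observations, plus 1% additive white
noise. `run_robustness()` repeats PINN training across weight
initializations and summarizes the spread of the recovered rates,
including learning curves with confidence bands.

## A worked example

```r
library(dinnr)

data <- sir_synthetic_data(seed = 1)   # 60 noisy days of the reference epidemic
head(data, 4)
#>       t     S     I      R
#> 1     0  997.  5.47 -1.86
#> 2     1  999.  1.46  5.03
#> 3     2  994.  3.63 -0.563
#> 4     3 1002.  3.66 -0.225

fit <- fit_simple_dinn(data, n_neurons = 5, seed = 1)
tidy(fit, beta_true = 0.5, sigma_true = 1/14)
#>   term  estimate   true rel_error
#> 1 beta    0.481  0.5       0.0375
#> 2 sigma   0.0692 0.0714    0.0306

pinn <- train_pinn(data, pinn_config(init_seed = 1))   # ~10 s
tidy(pinn, beta_true = 0.5, sigma_true = 1/14)
#>   term  estimate   true rel_error
#> 1 beta    0.495  0.5      0.00961
#> 2 sigma   0.0716 0.0714   0.00242
```

Both estimators recover the rates from data whose individual observations
are perturbed (note the negative early `R` values — noise is not clipped):
the 5-neuron finite-difference fit lands within ~4% of both rates, and the
full PINN within ~1%. `autoplot(pinn)` shows the reconstructed
trajectories over the observations; `run_robustness(data, n_runs = 30)`
followed by `autoplot()` / `plot_learning_curves()` reproduces the
spread-and-convergence analysis across initializations.

A thin command-line wrapper is installed as `exec/dinn`
(`dinn simulate`, `dinn fit-simple`, `dinn fit-pinn`, `dinn robustness`);
all artifacts are plain `t,S,I,R` CSV files with the resolved
configuration embedded as comment lines.

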