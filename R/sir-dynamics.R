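#' SIR model right-hand side
#'
#' Instantaneous rates of change of the three compartments of the classical
#' Kermack-McKendrick SIR model,
#' \deqn{dS/dt = -\beta S I / N, \quad dI/dt = \beta S I / N - \sigma I,
#'       \quad dR/dt = \sigma I,}
#' where `beta` is the transmission rate and `sigma` the recovery rate
#' (both 1/day), and `N` the (conserved) total population.
#'
#' @param S,I,R Compartment sizes (individuals). Finite scalars.
#' @param beta Transmission rate (1/day), non-negative.
#' @param sigma Recovery rate (1/day), non-negative.
#' @param N Total population (> 0).
#'
#' @return A named numeric vector `c(dS, dI, dR)` (individuals/day). The
#'   three components always sum to zero: the SIR flow conserves `N`.
#' @examples
#' sir_rhs(999, 1, 0, beta = 0.5, sigma = 1 / 14, N = 1000)
#' @export
sir_rhs <- function(S, I, R, beta, sigma, N) {
  check_sir_params(beta, sigma, N)
  if (!all(is.finite(c(S, I, R)))) {
    stop("state components S, I, R must be finite", call. = FALSE)
  }
  infection <- beta * S * I / N
  recovery <- sigma * I
  c(dS = -infection, dI = infection - recovery, dR = recovery)
}

check_sir_params <- function(beta, sigma, N) {
  if (!is.finite(beta) || beta < 0) stop("beta must be finite and >= 0", call. = FALSE)
  if (!is.finite(sigma) || sigma < 0) stop("sigma must be finite and >= 0", call. = FALSE)
  if (!is.finite(N) || N <= 0) stop("N must be finite and > 0", call. = FALSE)
  invisible(TRUE)
}

#' Construct an SIR trajectory table
#'
#' A trajectory is an ordinary tibble with columns `t`, `S`, `I`, `R` (one
#' row per observation time) carrying two attributes: `N`, the population
#' scale of the compartments, and `noisy`, whether measurement noise has
#' been applied. All model-fitting functions in the package accept these
#' tibbles.
#'
#' @param t Observation times in days, strictly increasing.
#' @param S,I,R Compartment values, same length as `t`.
#' @param N Population scale (> 0).
#' @param noisy Logical flag; clean trajectories satisfy the conservation
#'   and positivity invariants, noisy ones need not.
#'
#' @return A tibble of class `sir_trajectory`.
#' @export
sir_trajectory <- function(t, S, I, R, N, noisy = FALSE) {
  stopifnot(length(t) == length(S), length(S) == length(I), length(I) == length(R))
  if (length(t) > 1 && any(diff(t) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (!is.finite(N) || N <= 0) stop("N must be finite and > 0", call. = FALSE)
  out <- tibble::tibble(t = as.numeric(t), S = as.numeric(S),
                        I = as.numeric(I), R = as.numeric(R))
  attr(out, "N") <- as.numeric(N)
  attr(out, "noisy") <- isTRUE(noisy)
  class(out) <- c("sir_trajectory", class(out))
  out
}

#' @rdname sir_trajectory
#' @param data A data frame with columns `t`, `S`, `I`, `R`.
#' @export
as_sir_trajectory <- function(data, N = NULL, noisy = FALSE) {
  required <- c("t", "S", "I", "R")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop("data lacks column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(N)) {
    N <- attr(data, "N")
    if (is.null(N)) N <- round(data$S[1] + data$I[1] + data$R[1])
  }
  sir_trajectory(data$t, data$S, data$I, data$R, N = N, noisy = noisy)
}

#' Population scale of a trajectory
#'
#' @param traj An [sir_trajectory()].
#' @return The `N` attribute (a scalar).
#' @export
trajectory_N <- function(traj) {
  N <- attr(traj, "N")
  if (is.null(N)) stop("trajectory carries no N attribute; use as_sir_trajectory()",
                       call. = FALSE)
  N
}

#' Integrate the SIR model with classical Runge-Kutta
#'
#' Solves the SIR equations with the fixed-step fourth-order Runge-Kutta
#' scheme of [deSolve::ode()], stepping exactly on the requested time grid
#' (a daily grid by default). RK4 preserves the linear invariant
#' S + I + R = N to round-off, and on clean solutions S is non-increasing
#' and R non-decreasing.
#'
#' @inheritParams sir_rhs
#' @param S0,I0,R0 Initial compartment sizes; must sum to `N`.
#' @param times Time grid in days (strictly increasing). Default `0:59`,
#'   i.e. 60 daily observations.
#'
#' @return A clean [sir_trajectory()] on `times`.
#' @examples
#' traj <- integrate_sir(beta = 0.5, sigma = 1 / 14, N = 1000,
#'                       S0 = 999, I0 = 1, R0 = 0)
#' @export
integrate_sir <- function(beta, sigma, N, S0 = N - 1, I0 = 1, R0 = 0,
                          times = 0:59) {
  check_sir_params(beta, sigma, N)
  if (abs(S0 + I0 + R0 - N) > 1e-8 * N) {
    stop("initial condition must satisfy S0 + I0 + R0 = N", call. = FALSE)
  }
  rhs <- function(t, y, parms) {
    list(sir_rhs(y[1], y[2], y[3], parms$beta, parms$sigma, parms$N))
  }
  sol <- deSolve::ode(y = c(S = S0, I = I0, R = R0), times = times, func = rhs,
                      parms = list(beta = beta, sigma = sigma, N = N),
                      method = "rk4")
  sir_trajectory(sol[, "time"], sol[, "S"], sol[, "I"], sol[, "R"],
                 N = N, noisy = FALSE)
}

#' Add white measurement noise to a clean trajectory
#'
#' Perturbs every compartment at every observation time with independent,
#' additive Gaussian noise. The noise level is a dimensionless fraction;
#' what it is a fraction *of* is set by `mode`:
#' \describe{
#'   \item{`"series-sd"` (default)}{sd in compartment `c` is `level`
#'     times the standard deviation of that compartment's clean time
#'     series — "1% noise" perturbs each curve by 1% of its own overall
#'     variation. This is the scale consistent with the magnitude of the
#'     deviations in the package's reference data protocol.}
#'   \item{`"population"`}{sd = `level * N` in every compartment
#'     (equivalently `level` on the normalized scale).}
#'   \item{`"compartment"`}{sd = `level` times each compartment's own
#'     current value (proportional noise; note it can never perturb a
#'     zero value).}
#' }
#' No clipping or renormalization is applied: noisy values may be
#' negative or exceed `N`, and S + I + R need not equal `N`, exactly as
#' in raw surveillance-style data.
#'
#' @param traj A clean [sir_trajectory()].
#' @param level Noise level as a dimensionless fraction (e.g. `0.01` for
#'   "1% noise"). Must be >= 0.
#' @param seed Optional integer seed; given the same seed the perturbation
#'   is reproduced exactly and the caller's RNG state is left untouched.
#' @param mode Noise scale interpretation, see above.
#'
#' @return A noisy [sir_trajectory()] on the same grid.
#' @export
add_white_noise <- function(traj, level, seed = NULL,
                            mode = c("series-sd", "population", "compartment")) {
  mode <- match.arg(mode)
  if (!is.finite(level) || level < 0) {
    stop("noise level must be finite and >= 0", call. = FALSE)
  }
  if (isTRUE(attr(traj, "noisy"))) {
    stop("trajectory is already noisy; noise is added to clean data", call. = FALSE)
  }
  N <- trajectory_N(traj)
  if (level == 0) {
    return(traj)
  }
  n <- nrow(traj)
  draw <- function() {
    sd_mat <- switch(mode,
      "series-sd" = matrix(level * c(stats::sd(traj$S), stats::sd(traj$I),
                                     stats::sd(traj$R)),
                           n, 3, byrow = TRUE),
      "population" = matrix(level * N, n, 3),
      "compartment" = abs(cbind(traj$S, traj$I, traj$R)) * level
    )
    matrix(stats::rnorm(3L * n), n, 3) * sd_mat
  }
  eps <- if (is.null(seed)) draw() else with_local_seed(seed, draw())
  sir_trajectory(traj$t, traj$S + eps[, 1], traj$I + eps[, 2],
                 traj$R + eps[, 3], N = N, noisy = TRUE)
}

# Evaluate `expr` under a temporary RNG state so callers' streams are
# unaffected; reproducible for a given seed.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Normalize a trajectory to proportions
#'
#' Divides every compartment by the population scale `N`, giving
#' proportions of the population. The SIR equations are invariant under
#' this rescaling — `beta` and `sigma` are unchanged — so fits on the
#' normalized scale estimate the same rates.
#'
#' @param traj An [sir_trajectory()].
#' @return The trajectory on the proportion scale, with `N = 1`.
#'   Idempotent: normalizing twice equals normalizing once.
#' @export
normalize_trajectory <- function(traj) {
  N <- trajectory_N(traj)
  sir_trajectory(traj$t, traj$S / N, traj$I / N, traj$R / N,
                 N = 1, noisy = isTRUE(attr(traj, "noisy")))
}

#' Generate the standard synthetic noisy epidemic dataset
#'
#' Convenience wrapper reproducing the package's reference data protocol:
#' RK4 integration of the SIR model with `beta = 0.5`, `sigma = 1/14`,
#' `N = 1000`, initial condition (999, 1, 0), 60 daily observations, then
#' 1% additive white noise.
#'
#' @param seed Seed for the noise draw.
#' @param beta,sigma,N,S0,I0,R0 Model parameters and initial condition.
#' @param days Number of daily observations (grid `0:(days - 1)`).
#' @param noise Noise level fraction; `0` returns the clean trajectory.
#' @return An [sir_trajectory()].
#' @examples
#' head(sir_synthetic_data(seed = 1))
#' @export
sir_synthetic_data <- function(seed = 1L, beta = 0.5, sigma = 1 / 14,
                               N = 1000, S0 = 999, I0 = 1, R0 = 0,
                               days = 60, noise = 0.01) {
  clean <- integrate_sir(beta, sigma, N, S0, I0, R0, times = seq_len(days) - 1)
  if (noise == 0) clean else add_white_noise(clean, level = noise, seed = seed)
}

#' Read and write trajectory CSV files
#'
#' The interchange format is a plain CSV with header `t,S,I,R` and one row
#' per observation. Comment lines starting with `#` are permitted (and are
#' used by [write_sir_csv()] to embed provenance such as the resolved run
#' configuration).
#'
#' @param path File path.
#' @param N Population scale; if `NULL`, taken from an embedded
#'   `# N: <value>` comment when present, else the rounded sum of the
#'   first row.
#' @param noisy Whether the file holds noisy data; if `NULL`, taken from an
#'   embedded `# noisy: <true/false>` comment, defaulting to `TRUE`.
#' @return [read_sir_csv()] returns an [sir_trajectory()];
#'   [write_sir_csv()] returns `path` invisibly.
#' @export
read_sir_csv <- function(path, N = NULL, noisy = NULL) {
  if (!file.exists(path)) stop("no such data file: ", path, call. = FALSE)
  header <- readLines(path, n = 50L)
  header <- header[startsWith(header, "#")]
  pick <- function(key) {
    hit <- grep(paste0("^#\\s*", key, ":"), header, value = TRUE)
    if (length(hit) == 0) return(NULL)
    trimws(sub(paste0("^#\\s*", key, ":"), "", hit[1]))
  }
  if (is.null(N) && !is.null(pick("N"))) N <- as.numeric(pick("N"))
  if (is.null(noisy)) {
    noisy <- if (is.null(pick("noisy"))) TRUE else tolower(pick("noisy")) == "true"
  }
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  as_sir_trajectory(as.data.frame(df), N = N, noisy = noisy)
}

#' @rdname read_sir_csv
#' @param traj An [sir_trajectory()].
#' @param comments Optional character vector written as `# `-prefixed
#'   comment lines before the header (provenance block).
#' @export
write_sir_csv <- function(traj, path, comments = NULL) {
  lines <- c(
    paste0("# ", c(comments,
                   paste0("N: ", format(trajectory_N(traj), digits = 15)),
                   paste0("noisy: ", tolower(isTRUE(attr(traj, "noisy")))))),
    "t,S,I,R",
    sprintf("%s,%s,%s,%s",
            format(traj$t, digits = 15, trim = TRUE, scientific = FALSE),
            format(traj$S, digits = 15, trim = TRUE),
            format(traj$I, digits = 15, trim = TRUE),
            format(traj$R, digits = 15, trim = TRUE))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @export
autoplot.sir_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), c("S", "I", "R"),
                              names_to = "compartment", values_to = "count")
  long$compartment <- factor(long$compartment, levels = c("S", "I", "R"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$count,
                                     colour = .data$compartment)) +
    (if (isTRUE(attr(object, "noisy"))) ggplot2::geom_point(size = 0.8)
     else ggplot2::geom_line()) +
    ggplot2::labs(x = "time (days)", y = "individuals", colour = NULL)
}
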