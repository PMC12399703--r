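#' Initialization-robustness study of the PINN inverse problem
#'
#' Trains the physics-informed network repeatedly on one shared dataset,
#' varying only the weight-initialization seed (run `k` uses
#' `seed_base + k`), and aggregates the recovered epidemic rates across
#' runs. A failed run is recorded in its row with its error message —
#' never silently dropped — and flagged in the aggregates.
#'
#' @param data An [sir_trajectory()], fixed across runs.
#' @param n_runs Number of trainings (the reference study uses 30).
#' @param seed_base Base seed; run seeds are `seed_base + 1 .. seed_base +
#'   n_runs`, all distinct.
#' @param config A [pinn_config()] shared by every run (its `init_seed` is
#'   overridden per run).
#' @param beta_true,sigma_true True rates for the relative errors.
#' @param regenerate_data If `TRUE`, each run also redraws the noise with
#'   seed `seed_base + k` via [sir_synthetic_data()]'s protocol applied to
#'   `data`'s clean counterpart — a broader robustness notion. Default
#'   `FALSE`: only the initialization varies.
#' @return An object of class `robustness_summary`: per-run tibble `runs`,
#'   the list of training traces, aggregate statistics (mean, sd, median,
#'   quartiles of each quantity; sample sd with `n - 1` denominator), the
#'   resolved configuration and run count. Methods: [tidy()], [glance()],
#'   [autoplot()], [render_reports()].
#' @export
run_robustness <- function(data, n_runs = 30, seed_base = 0,
                           config = pinn_config(), beta_true = 0.5,
                           sigma_true = 1 / 14, regenerate_data = FALSE) {
  if (n_runs < 1) stop("n_runs must be >= 1", call. = FALSE)
  rows <- vector("list", n_runs)
  traces <- vector("list", n_runs)
  for (k in seq_len(n_runs)) {
    seed_k <- seed_base + k
    cfg <- config
    cfg$init_seed <- as.integer(seed_k)
    data_k <- if (regenerate_data) {
      add_white_noise(attr(data, "clean") %||% data, level = 0.01, seed = seed_k)
    } else {
      data
    }
    fit <- tryCatch(train_pinn(data_k, cfg), error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[k]] <- tibble::tibble(
        run = k, init_seed = seed_k, ok = FALSE,
        beta_hat = NA_real_, sigma_hat = NA_real_,
        rel_err_beta = NA_real_, rel_err_sigma = NA_real_,
        final_loss = NA_real_, error = conditionMessage(fit))
      traces[[k]] <- attr(fit, "trace_so_far")
    } else {
      fin <- fit$trace[nrow(fit$trace), ]
      rows[[k]] <- tibble::tibble(
        run = k, init_seed = seed_k, ok = TRUE,
        beta_hat = fit$lambda_hat[["beta"]],
        sigma_hat = fit$lambda_hat[["sigma"]],
        rel_err_beta = relative_error(fit$lambda_hat[["beta"]], beta_true),
        rel_err_sigma = relative_error(fit$lambda_hat[["sigma"]], sigma_true),
        final_loss = fin$total, error = NA_character_)
      traces[[k]] <- fit$trace
    }
  }
  runs <- dplyr::bind_rows(rows)
  structure(list(
    runs = runs,
    traces = traces,
    aggregates = robustness_aggregates(runs),
    config = config,
    seed_base = seed_base,
    n_runs = n_runs,
    n_ok = sum(runs$ok),
    beta_true = beta_true,
    sigma_true = sigma_true
  ), class = "robustness_summary")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Cross-run statistics of every per-run quantity; sd is the sample
# standard deviation (n - 1 denominator).
robustness_aggregates <- function(runs) {
  ok <- dplyr::filter(runs, .data$ok)
  metrics <- c("beta_hat", "sigma_hat", "rel_err_beta", "rel_err_sigma",
               "final_loss")
  long <- tidyr::pivot_longer(ok[, c("run", metrics)], dplyr::all_of(metrics),
                              names_to = "metric", values_to = "value")
  dplyr::summarise(
    dplyr::group_by(long, .data$metric),
    n = dplyr::n(),
    mean = mean(.data$value),
    sd = stats::sd(.data$value),
    median = stats::median(.data$value),
    q25 = unname(stats::quantile(.data$value, 0.25)),
    q75 = unname(stats::quantile(.data$value, 0.75)),
    .groups = "drop"
  )
}

#' @export
print.robustness_summary <- function(x, ...) {
  cat(sprintf("PINN robustness study: %d runs (%d succeeded), seed base %s\n",
              x$n_runs, x$n_ok, format(x$seed_base)))
  print(x$aggregates)
  invisible(x)
}

#' @export
tidy.robustness_summary <- function(x, ...) x$aggregates

#' @export
glance.robustness_summary <- function(x, ...) {
  pick <- function(metric, stat) {
    v <- x$aggregates[x$aggregates$metric == metric, ][[stat]]
    if (length(v) == 0) NA_real_ else v
  }
  tibble::tibble(n_runs = x$n_runs, n_ok = x$n_ok,
                 mean_beta = pick("beta_hat", "mean"),
                 sd_beta = pick("beta_hat", "sd"),
                 mean_sigma = pick("sigma_hat", "mean"),
                 sd_sigma = pick("sigma_hat", "sd"),
                 mean_rel_err_beta = pick("rel_err_beta", "mean"),
                 mean_rel_err_sigma = pick("rel_err_sigma", "mean"))
}

#' Cross-run learning curves with a confidence band
#'
#' Aligns the training traces of repeated runs on their common recording
#' grid and computes, per recorded iteration and parameter, the cross-run
#' mean and a normal-approximation confidence band
#' `mean +/- z * sd / sqrt(n)`.
#'
#' @param traces A list of training traces (as in `pinn_fit$trace`), or a
#'   `robustness_summary`.
#' @param confidence Band coverage, default 0.95.
#' @return A tibble with columns `iteration`, `parameter` (`beta`,
#'   `sigma`), `mean`, `sd`, `lower`, `upper`, `n`.
#' @export
summarize_learning_curves <- function(traces, confidence = 0.95) {
  if (inherits(traces, "robustness_summary")) traces <- traces$traces
  traces <- traces[!vapply(traces, is.null, logical(1))]
  if (length(traces) == 0) stop("no traces to summarize", call. = FALSE)
  grid <- traces[[1]]$iteration
  same <- vapply(traces, function(tr) identical(tr$iteration, grid), logical(1))
  if (!all(same)) {
    stop("traces do not share a common recording grid", call. = FALSE)
  }
  z <- stats::qnorm((1 + confidence) / 2)
  long <- dplyr::bind_rows(lapply(seq_along(traces), function(k) {
    tr <- traces[[k]]
    tibble::tibble(run = k, iteration = tr$iteration,
                   beta = tr$beta_hat, sigma = tr$sigma_hat)
  }))
  long <- tidyr::pivot_longer(long, c("beta", "sigma"),
                              names_to = "parameter", values_to = "value")
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$iteration, .data$parameter),
    mean = mean(.data$value), sd = stats::sd(.data$value),
    n = dplyr::n(), .groups = "drop"
  )
  se <- ifelse(out$n > 1, out$sd / sqrt(out$n), 0)
  out$sd <- ifelse(out$n > 1, out$sd, 0)
  out$lower <- out$mean - z * se
  out$upper <- out$mean + z * se
  out
}

#' @export
autoplot.robustness_summary <- function(object, ...) {
  ok <- dplyr::filter(object$runs, .data$ok)
  long <- tidyr::pivot_longer(ok, c("rel_err_beta", "rel_err_sigma"),
                              names_to = "parameter", values_to = "rel_error")
  long$parameter <- factor(long$parameter, levels = c("rel_err_beta", "rel_err_sigma"),
                           labels = c("beta", "sigma"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$parameter, y = .data$rel_error)) +
    ggplot2::geom_violin(fill = "grey85", colour = NA) +
    ggplot2::geom_boxplot(width = 0.15, outlier.size = 0.7) +
    ggplot2::labs(x = NULL, y = "relative error",
                  title = sprintf("Relative error across %d initializations",
                                  object$n_ok))
}

#' Plot cross-run learning curves
#'
#' @param curves Output of [summarize_learning_curves()] (or a
#'   `robustness_summary`, summarized on the fly).
#' @param beta_true,sigma_true Optional true rates drawn as horizontal
#'   reference lines.
#' @return A ggplot object: mean estimate per iteration with the
#'   confidence band, one panel per parameter.
#' @export
plot_learning_curves <- function(curves, beta_true = NULL, sigma_true = NULL) {
  if (inherits(curves, "robustness_summary")) {
    if (is.null(beta_true)) beta_true <- curves$beta_true
    if (is.null(sigma_true)) sigma_true <- curves$sigma_true
    curves <- summarize_learning_curves(curves)
  }
  p <- ggplot2::ggplot(curves, ggplot2::aes(x = .data$iteration, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = "estimated rate (1/day)")
  if (!is.null(beta_true) && !is.null(sigma_true)) {
    ref <- tibble::tibble(parameter = c("beta", "sigma"),
                          truth = c(beta_true, sigma_true))
    p <- p + ggplot2::geom_hline(data = ref,
                                 ggplot2::aes(yintercept = .data$truth),
                                 colour = "darkorange", linetype = 2)
  }
  p
}

#' Write the robustness study's report artifacts
#'
#' Writes deterministic filenames into `outdir`: `runs.csv` (per-run
#' results), `summary.csv` (aggregate statistics), `relative_errors.png`
#' (boxplot/violin of the relative errors) and `learning_curves.png`
#' (cross-run mean curves with the 95% band).
#'
#' @param summary A `robustness_summary` with at least one completed run.
#' @param outdir Output directory (created if absent; must be writable).
#' @return Invisibly, the paths written (2 CSV + 2 figure files).
#' @export
render_reports <- function(summary, outdir) {
  if (!inherits(summary, "robustness_summary") || summary$n_ok == 0) {
    stop("summary must be a robustness_summary with at least one completed run",
         call. = FALSE)
  }
  ok <- dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir,
                                call. = FALSE)
  paths <- file.path(outdir, c("runs.csv", "summary.csv",
                               "relative_errors.png", "learning_curves.png"))
  readr::write_csv(summary$runs, paths[1])
  readr::write_csv(summary$aggregates, paths[2])
  ggplot2::ggsave(paths[3], ggplot2::autoplot(summary),
                  width = 6, height = 4, dpi = 120)
  ggplot2::ggsave(paths[4], plot_learning_curves(summary),
                  width = 7, height = 4, dpi = 120)
  invisible(paths)
}
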