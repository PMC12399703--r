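#' Default end-to-end run configuration
#'
#' The defaults reproduce the package's reference protocol: an SIR
#' epidemic with `beta = 0.5`, `sigma = 1/14` in a population of 1000
#' (initial state 999/1/0), 60 daily observations with 1% additive white
#' noise; the simple DINN with 5 neurons and 20 restarts; the PINN with
#' a 3 x 64 ReLU network, Adam at learning rate 0.001 and 30,000
#' iterations; and a 30-run robustness study.
#'
#' @return A nested named list, fully serializable to YAML.
#' @export
default_run_config <- function() {
  list(
    simulate = list(beta = 0.5, sigma = 1 / 14, N = 1000, S0 = 999, I0 = 1,
                    R0 = 0, days = 60L, noise = 0.01, seed = 1L),
    fit_simple = list(neurons = 5L, restarts = 20L, seed = 1L),
    fit_pinn = list(layers = c(64L, 64L, 64L), learning_rate = 0.001,
                    iterations = 30000L, trace_every = 100L, seed = 1L),
    robustness = list(runs = 30L, seed_base = 0L),
    outdir = ".",
    log_level = "info"
  )
}

#' Load and save run configurations
#'
#' Configurations are YAML files mirroring [default_run_config()]. Absent
#' keys take their default values; unknown keys are rejected by name, so
#' a typo cannot silently fall back to a default.
#'
#' @param path Path to a YAML file.
#' @return [load_run_config()] returns the merged configuration list;
#'   [save_run_config()] writes it and returns `path` invisibly.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  user <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop("cannot parse config ", path, ": ", conditionMessage(e), call. = FALSE)
  })
  merge_config(default_run_config(), user %||% list(), prefix = character())
}

#' @rdname load_run_config
#' @param config A configuration list.
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}

merge_config <- function(defaults, user, prefix) {
  if (length(user) == 0) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    full <- paste(c(prefix, unknown[1]), collapse = ".")
    stop("unknown configuration key: ", full, call. = FALSE)
  }
  for (key in names(user)) {
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      defaults[[key]] <- merge_config(defaults[[key]],
                                      as.list(user[[key]]), c(prefix, key))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

# yaml-formatted comment block used to embed the resolved configuration
# (provenance) in CSV artifacts.
config_comment_lines <- function(config) {
  strsplit(yaml::as.yaml(config, precision = 15), "\n", fixed = TRUE)[[1]]
}
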