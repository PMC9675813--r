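CONFIG_DEFAULTS <- list(
  a = 0.5, b = 0.5, D = 5L, d = 1, I = 0.5,
  change_prob = 0.2, steps = 1000L, replicates = 100L,
  seed = 1L, seed_network = 1L, seed_disease = 2L, seed_env = 3L,
  a_grid = round(seq(0, 1, by = 0.1), 10), I_grid = round(seq(0, 1, by = 0.1), 10),
  b_grid = NULL, lambda_bins = 10L,
  redraw_disease_per_replicate = TRUE)

CONFIG_KEYS <- c("H", "L", names(CONFIG_DEFAULTS))

#' Default experiment configuration
#'
#' Builds a validated configuration list. `H` and `L` are required; all
#' other parameters default to the standard study conditions: gate ratio
#' `a = 0.5`, branching `b = 0.5`, `D = 5` defect nodes in one cluster
#' (`d = 1`), input activity `I = 0.5`, per-bit change probability 0.2,
#' 1000 steps and 100 replicates, plus a master `seed` (for sweeps) and
#' three independent stream seeds (network, disease, environment) for single
#' runs.
#'
#' @param H,L lattice dimensions.
#' @param ... overrides for any configuration key.
#' @return A validated configuration list of class `experiment_config`.
#' @examples
#' cfg <- default_config(H = 10, L = 10, a = 0.3, I = 0.8)
#' cfg$steps
#' @export
default_config <- function(H, L, ...) {
  as_config(c(list(H = H, L = L), list(...)))
}

# Validate a raw config list: unknown keys rejected, defaults applied,
# ranges checked with the offending key named.
as_config <- function(config) {
  if (inherits(config, "experiment_config")) return(config)
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), CONFIG_KEYS)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  for (k in c("H", "L")) {
    if (is.null(config[[k]])) {
      stop(sprintf("configuration key `%s` is required", k), call. = FALSE)
    }
  }
  for (k in names(CONFIG_DEFAULTS)) {
    if (is.null(config[[k]])) config[[k]] <- CONFIG_DEFAULTS[[k]]
  }
  if (is.null(config$b_grid)) config$b_grid <- config$b
  config$H <- check_count(config$H, "H")
  config$L <- check_count(config$L, "L")
  for (k in c("a", "b", "d", "I", "change_prob")) {
    config[[k]] <- check_fraction(config[[k]], k)
  }
  config$D <- check_count(config$D, "D", min = 0L)
  if (config$D > config$H * config$L) {
    stop("`D` exceeds the number of lattice nodes", call. = FALSE)
  }
  config$steps <- check_count(config$steps, "steps")
  config$replicates <- check_count(config$replicates, "replicates")
  config$lambda_bins <- check_count(config$lambda_bins, "lambda_bins")
  for (k in c("seed", "seed_network", "seed_disease", "seed_env")) {
    config[[k]] <- check_count(config[[k]], k, min = 0L)
  }
  for (k in c("a_grid", "I_grid", "b_grid")) {
    v <- config[[k]]
    if (!is.numeric(v) || any(is.na(v)) || any(v < 0 | v > 1)) {
      stop(sprintf("`%s` must be numeric values in [0, 1]", k), call. = FALSE)
    }
    config[[k]] <- as.numeric(v)
  }
  if (!is.logical(config$redraw_disease_per_replicate) ||
      length(config$redraw_disease_per_replicate) != 1L) {
    stop("`redraw_disease_per_replicate` must be TRUE or FALSE", call. = FALSE)
  }
  config <- config[CONFIG_KEYS]
  class(config) <- "experiment_config"
  config
}

#' Load an experiment configuration from JSON or YAML
#'
#' The format is chosen by file extension (`.json` vs `.yml`/`.yaml`).
#' Unknown keys are rejected and out-of-range values reported with the
#' offending key named; missing keys get the defaults of [default_config()].
#'
#' @param path path to a JSON or YAML configuration file.
#' @return A validated `experiment_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.list(raw)) stop("config file must contain a mapping of keys",
                          call. = FALSE)
  as_config(raw)
}

#' Write an experiment configuration
#'
#' @param config an `experiment_config` (or raw list).
#' @param path output path ending in `.json`, `.yml` or `.yaml`.
#' @return `path`, invisibly. Reloading with [load_config()] gives an
#'   identical configuration.
#' @export
write_config <- function(config, path) {
  config <- as_config(config)
  x <- unclass(config)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("<experiment_config> H=%d L=%d a=%.3g b=%.3g D=%d d=%.3g I=%.3g\n",
              x$H, x$L, x$a, x$b, x$D, x$d, x$I))
  cat(sprintf("  change_prob=%.3g steps=%d replicates=%d seeds(net/dis/env)=%d/%d/%d master=%d\n",
              x$change_prob, x$steps, x$replicates,
              x$seed_network, x$seed_disease, x$seed_env, x$seed))
  invisible(x)
}
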