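STEP_CASES <- c("A", "B", "C", "D")
RUN_CATEGORIES <- c("A", "B", "C", "Cx", "D", "Dx")

#' Classify one time step from the two output vectors
#'
#' Compares the healthy and the defect network output for the same input:
#' case `D` if the healthy output is zero (the environment is lethal even for
#' the healthy network), case `A` if both outputs are equal (no symptoms),
#' case `C` if only the defect output is zero (lethal disease), case `B`
#' otherwise (reduced but non-zero output: symptomatic disease).
#'
#' Because the model has only AND/OR gates, the defect network's active
#' outputs are always a subset of the healthy ones; a violation indicates a
#' propagation bug and aborts.
#'
#' @param healthy_out,defect_out binary (0/1) vectors of equal length.
#' @return One of `"A"`, `"B"`, `"C"`, `"D"`.
#' @export
classify_step <- function(healthy_out, defect_out) {
  h <- as.integer(healthy_out)
  f <- as.integer(defect_out)
  if (length(h) != length(f)) {
    stop("healthy and defect outputs must have equal length", call. = FALSE)
  }
  if (any(f > h)) {
    stop(paste("subset property violated: defect network active where the",
               "healthy network is not (propagation bug)"), call. = FALSE)
  }
  if (!any(h == 1L)) return("D")
  if (identical(h, f)) return("A")
  if (!any(f == 1L)) return("C")
  "B"
}

# Vectorized step classification over n x H output matrices.
classify_steps <- function(healthy_mat, defect_mat) {
  if (any(defect_mat > healthy_mat)) {
    stop(paste("subset property violated: defect network active where the",
               "healthy network is not (propagation bug)"), call. = FALSE)
  }
  hs <- rowSums(healthy_mat)
  fs <- rowSums(defect_mat)
  equal <- rowSums(healthy_mat != defect_mat) == 0L
  ifelse(hs == 0, "D", ifelse(equal, "A", ifelse(fs == 0, "C", "B")))
}

#' Run a healthy-versus-defect time series
#'
#' At every step the current environment vector is propagated through both
#' the healthy network (empty defect set) and the defect network; the two
#' output strengths and the step case A/B/C/D are recorded, then the
#' environment fluctuates. Lethal steps (C/D) are per-step phenotype labels,
#' not absorbing states: the series continues, so one time line can contain
#' all four cases.
#'
#' @param net a [lattice_network][build_lattice].
#' @param ds a [defect_set][place_defects] (or `NULL` for none).
#' @param env an [environment_process][init_inputs] with matching `H`.
#' @param steps number of time steps.
#' @return A `timeseries_result`: list with `records` (data.frame with
#'   columns `t`, `n_active_inputs`, `healthy_strength`, `defect_strength`,
#'   `case`) and `config` (the parameters and seeds used).
#'
#' @examples
#' net <- build_lattice(10, 10, a = 0.4, b = 0.6, seed = 1)
#' ds <- place_defects(net, D = 4, d = 1, seed = 2)
#' env <- init_inputs(10, I = 0.7, seed = 3)
#' ts <- run_timeseries(net, ds, env, steps = 200)
#' ts
#' table(ts$records$case)
#' @export
run_timeseries <- function(net, ds, env, steps) {
  stopifnot(inherits(net, "lattice_network"),
            inherits(env, "environment_process"))
  steps <- check_count(steps, "steps")
  if (env$H != net$H) {
    stop("environment width does not match the network's H", call. = FALSE)
  }
  if (is.null(ds)) ds <- empty_defects(net)
  mask <- defect_mask(net, ds)

  inputs <- env_input_matrix(env, steps)$inputs
  healthy_out <- last_layer(propagate_layers(net, matrix(FALSE, net$H, net$L),
                                             inputs))
  defect_out <- last_layer(propagate_layers(net, mask, inputs))
  cases <- classify_steps(healthy_out, defect_out)

  records <- data.frame(
    t = seq_len(steps),
    n_active_inputs = as.integer(rowSums(inputs)),
    healthy_strength = as.integer(rowSums(healthy_out)),
    defect_strength = as.integer(rowSums(defect_out)),
    case = cases,
    stringsAsFactors = FALSE)

  structure(
    list(records = records,
         config = list(H = net$H, L = net$L, a = net$a, b = net$b,
                       D = ds$D, d = ds$d, I = env$I,
                       change_prob = env$change_prob, steps = steps,
                       seed_network = net$seed, seed_disease = ds$seed,
                       seed_env = env$seed)),
    class = "timeseries_result")
}

last_layer <- function(layers) layers[[length(layers)]]

#' @export
print.timeseries_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<timeseries_result> %d steps, H=%d L=%d a=%.3g b=%.3g D=%d d=%.3g I=%.3g\n",
              cfg$steps, cfg$H, cfg$L, cfg$a, cfg$b, cfg$D, cfg$d, cfg$I))
  tb <- table(factor(x$records$case, levels = STEP_CASES))
  cat("  step cases: ",
      paste(sprintf("%s=%d", names(tb), tb), collapse = " "),
      "  (run category ", classify_run(x$records$case), ")\n", sep = "")
  invisible(x)
}

#' Classify a whole time line into a run category
#'
#' A pure function of the *set* of step cases present: if case D occurred the
#' run is `Dx` when A, B and C all occurred as well, otherwise `D`; else if C
#' occurred it is `Cx` when both A and B occurred, otherwise `C`; else `B` if
#' any symptomatic step occurred, else `A`.
#'
#' @param cases character vector of step cases (`"A"`/`"B"`/`"C"`/`"D"`).
#' @return One of `"A"`, `"B"`, `"C"`, `"Cx"`, `"D"`, `"Dx"`.
#' @export
classify_run <- function(cases) {
  if (length(cases) == 0L) stop("empty case sequence", call. = FALSE)
  if (!all(cases %in% STEP_CASES)) stop("invalid step case", call. = FALSE)
  present <- unique(cases)
  if ("D" %in% present) {
    if (all(c("A", "B", "C") %in% present)) "Dx" else "D"
  } else if ("C" %in% present) {
    if (all(c("A", "B") %in% present)) "Cx" else "C"
  } else if ("B" %in% present) {
    "B"
  } else {
    "A"
  }
}

#' Episode-length (incidence) distributions of a time line
#'
#' Run-length encodes the case sequence: maximal consecutive runs of case B
#' are symptomatic episodes, maximal runs of case A are symptom-free
#' episodes. Lethal steps (C/D) break episodes and belong to neither
#' distribution, so the episode lengths plus the lethal step counts always
#' add up to the series length.
#'
#' @param cases character vector of step cases.
#' @return An `episode_distributions` object: list with integer vectors
#'   `symptomatic_lengths` and `asymptomatic_lengths` and the counts
#'   `n_lethal_disease` (C steps) and `n_lethal_environment` (D steps).
#' @export
episode_distributions <- function(cases) {
  if (length(cases) == 0L) stop("empty case sequence", call. = FALSE)
  if (!all(cases %in% STEP_CASES)) stop("invalid step case", call. = FALSE)
  r <- rle(cases)
  structure(
    list(symptomatic_lengths = r$lengths[r$values == "B"],
         asymptomatic_lengths = r$lengths[r$values == "A"],
         n_lethal_disease = sum(cases == "C"),
         n_lethal_environment = sum(cases == "D")),
    class = "episode_distributions")
}

#' @export
print.episode_distributions <- function(x, ...) {
  cat(sprintf("<episode_distributions> %d symptomatic episode(s), %d symptom-free episode(s)\n",
              length(x$symptomatic_lengths), length(x$asymptomatic_lengths)))
  cat(sprintf("  lethal steps: %d disease (C), %d environment (D)\n",
              x$n_lethal_disease, x$n_lethal_environment))
  invisible(x)
}

#' Chronic-versus-acute signature of a time line
#'
#' A persistent case-B deficit reads as a chronic disease (high `b_fraction`,
#' low switching); intermittent switching between cases A and B reads as an
#' acute disease (high `ab_switch_rate`). Both metrics are reported
#' continuously rather than thresholded into labels.
#'
#' @param cases character vector of step cases.
#' @return List with `b_fraction` (share of B steps) and `ab_switch_rate`
#'   (share of adjacent step pairs that switch A->B or B->A; 0 for a length-1
#'   series).
#' @export
chronicity_metrics <- function(cases) {
  if (length(cases) == 0L) stop("empty case sequence", call. = FALSE)
  if (!all(cases %in% STEP_CASES)) stop("invalid step case", call. = FALSE)
  n <- length(cases)
  b_fraction <- sum(cases == "B") / n
  if (n == 1L) {
    switch_rate <- 0
  } else {
    from <- cases[-n]
    to <- cases[-1L]
    switch_rate <- sum((from == "A" & to == "B") | (from == "B" & to == "A")) /
      (n - 1L)
  }
  list(b_fraction = b_fraction, ab_switch_rate = switch_rate)
}

# One replicate run under a config with explicit seeds; returns the run
# category and the defect set's average location.
run_replicate <- function(config, seed_network, seed_disease, seed_env) {
  net <- build_lattice(config$H, config$L, config$a, config$b, seed_network)
  ds <- place_defects(net, config$D, config$d, seed_disease)
  env <- init_inputs(config$H, config$I, seed_env,
                     change_prob = config$change_prob)
  ts <- run_timeseries(net, ds, env, config$steps)
  list(category = classify_run(ts$records$case),
       lambda = if (config$D > 0) average_location(ds, net) else NA_real_)
}

category_fractions <- function(categories) {
  tb <- table(factor(categories, levels = RUN_CATEGORIES))
  stats::setNames(as.numeric(tb) / length(categories), RUN_CATEGORIES)
}

#' Sweep the input activity I
#'
#' For each value of the input activity on a grid, simulates `replicates`
#' independent time lines (fresh network, defect placement and environment
#' seeds per replicate) and reports the fraction of runs falling in each run
#' category A/B/C/Cx/D/Dx.
#'
#' @param config experiment configuration, see [default_config()].
#' @param I_grid numeric vector of input-activity values in `[0, 1]`.
#' @param replicates runs per grid value (default from `config`).
#' @return data.frame with columns `I`, `n`, and one fraction column per run
#'   category; the six fractions in each row sum to 1.
#' @export
sweep_input_activity <- function(config, I_grid, replicates = config$replicates) {
  config <- as_config(config)
  replicates <- check_count(replicates, "replicates")
  stopifnot(all(I_grid >= 0 & I_grid <= 1))
  rows <- lapply(seq_along(I_grid), function(i) {
    cfg <- config
    cfg$I <- I_grid[i]
    cats <- replicate_categories(cfg, replicates, stream = i)$category
    fr <- category_fractions(cats)
    c(list(I = I_grid[i], n = replicates), as.list(fr))
  })
  assemble_sweep(rows)
}

#' Sweep the AND-gate ratio a
#'
#' Like [sweep_input_activity()] but varying the gate ratio `a`, the control
#' parameter of the model's percolation-like phase transition. Also reports
#' the dominant (most frequent) run category per grid value, with ties
#' broken toward the lexicographically earlier label.
#'
#' @param config experiment configuration.
#' @param a_grid numeric vector of gate-ratio values in `[0, 1]`.
#' @param replicates runs per grid value.
#' @return data.frame with columns `a`, `n`, the six category fractions and
#'   `dominant`.
#' @export
sweep_gate_ratio <- function(config, a_grid, replicates = config$replicates) {
  config <- as_config(config)
  replicates <- check_count(replicates, "replicates")
  stopifnot(all(a_grid >= 0 & a_grid <= 1))
  rows <- lapply(seq_along(a_grid), function(i) {
    cfg <- config
    cfg$a <- a_grid[i]
    cats <- replicate_categories(cfg, replicates, stream = i)$category
    fr <- category_fractions(cats)
    dom <- RUN_CATEGORIES[which.max(fr)]
    c(list(a = a_grid[i], n = replicates), as.list(fr), list(dominant = dom))
  })
  assemble_sweep(rows)
}

#' Sweep the average damage location lambda
#'
#' Simulates `replicates` time lines per `(a, b)` cell; each replicate's
#' average defect location lambda is computed from its own defect set and
#' binned into `lambda_bins` equal-width bins over `[1/L, 1]`. Category
#' fractions are reported per `(a, b, bin)` cell; bins no replicate fell
#' into are kept with `n = 0` and `NA` fractions rather than fabricated.
#'
#' @param config experiment configuration (its `a` and `b` are used unless
#'   grids are given).
#' @param replicates runs per `(a, b)` cell.
#' @param a_grid,b_grid parameter grids (default: the single configured value).
#' @param lambda_bins number of equal-width lambda bins (default 10).
#' @return data.frame with columns `a`, `b`, `lambda_bin`, `lambda_lo`,
#'   `lambda_hi`, `n` and the six category-fraction columns.
#' @export
sweep_location <- function(config, replicates = config$replicates,
                           a_grid = config$a, b_grid = config$b,
                           lambda_bins = 10L) {
  config <- as_config(config)
  replicates <- check_count(replicates, "replicates")
  lambda_bins <- check_count(lambda_bins, "lambda_bins")
  if (config$D < 1L) stop("location sweep needs D >= 1", call. = FALSE)
  lo <- 1 / config$L
  breaks <- seq(lo, 1, length.out = lambda_bins + 1L)
  grid <- expand.grid(a = a_grid, b = b_grid, KEEP.OUT.ATTRS = FALSE)
  rows <- list()
  for (g in seq_len(nrow(grid))) {
    cfg <- config
    cfg$a <- grid$a[g]
    cfg$b <- grid$b[g]
    reps <- replicate_categories(cfg, replicates, stream = g)
    bin <- findInterval(reps$lambda, breaks, rightmost.closed = TRUE,
                        all.inside = TRUE)
    for (bb in seq_len(lambda_bins)) {
      in_bin <- bin == bb
      fr <- if (any(in_bin)) category_fractions(reps$category[in_bin]) else
        stats::setNames(rep(NA_real_, length(RUN_CATEGORIES)), RUN_CATEGORIES)
      rows[[length(rows) + 1L]] <- c(
        list(a = grid$a[g], b = grid$b[g], lambda_bin = bb,
             lambda_lo = breaks[bb], lambda_hi = breaks[bb + 1L],
             n = sum(in_bin)),
        as.list(fr))
    }
  }
  assemble_sweep(rows)
}

# Run `replicates` independent time lines of a config; seeds are derived
# deterministically from config$seed and the stream index.
replicate_categories <- function(config, replicates, stream = 1L) {
  seeds <- derive_seeds(config$seed + stream, 3L * replicates)
  cats <- character(replicates)
  lambdas <- numeric(replicates)
  for (r in seq_len(replicates)) {
    s <- seeds[(3L * (r - 1L) + 1L):(3L * r)]
    res <- run_replicate(config, s[1L], s[2L], s[3L])
    cats[r] <- res$category
    lambdas[r] <- res$lambda
  }
  list(category = cats, lambda = lambdas)
}

assemble_sweep <- function(rows) {
  df <- do.call(rbind, lapply(rows, as.data.frame, stringsAsFactors = FALSE))
  rownames(df) <- NULL
  df
}

#' Locate the phase transition in the gate ratio
#'
#' Given a gate-ratio sweep with a dominant run category per grid value
#' (columns `a` and `dominant`, `a` ascending), returns the midpoint between
#' the largest `a` whose dominant category is non-lethal (`A`, `B` or `Cx`)
#' and the smallest larger `a` whose dominant category is lethal (`D` or
#' `Dx`). Errors if the grid contains no such flip.
#'
#' @param sweep data.frame with columns `a` and `dominant`, e.g. from
#'   [sweep_gate_ratio()].
#' @return The estimated critical gate ratio.
#' @export
estimate_transition <- function(sweep) {
  stopifnot(is.data.frame(sweep), all(c("a", "dominant") %in% names(sweep)))
  sweep <- sweep[order(sweep$a), , drop = FALSE]
  nonlethal <- sweep$dominant %in% c("A", "B", "Cx")
  lethal <- sweep$dominant %in% c("D", "Dx")
  if (!any(nonlethal)) stop("no transition detected: no non-lethal-dominated grid point",
                            call. = FALSE)
  a_lo <- max(sweep$a[nonlethal])
  above <- lethal & sweep$a > a_lo
  if (!any(above)) stop("no transition detected: no lethal-dominated grid point above",
                        call. = FALSE)
  a_hi <- min(sweep$a[above])
  (a_lo + a_hi) / 2
}
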