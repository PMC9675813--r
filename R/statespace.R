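#' Exhaustively enumerate the state space of a network
#'
#' Propagates all `2^N` possible input vectors (`N = H`) through the
#' network, layer by layer. Because the evaluation is deterministic, a state
#' at one layer maps to exactly one state at the next, while several states
#' can merge onto the same successor; the per-layer number of distinct
#' states is therefore non-increasing: the funnelling that maps many
#' environments onto few phenotypes.
#'
#' Inputs are ordered by the binary number they represent; an input or layer
#' state is encoded as an integer whose bit `k - 1` is the state of pathway
#' `k` (pathway 1 is the least significant bit).
#'
#' @param net a [lattice_network][build_lattice] with `H <= max_n`.
#' @param ds a [defect_set][place_defects] or `NULL`.
#' @param max_n enumeration budget guard: refuse `H > max_n` (default 20)
#'   rather than attempt `2^H` propagations by exhaustion.
#' @return A `statespace_result`: list with `N`, `inputs` (the `2^N` input
#'   codes 0..2^N-1), `layer_codes` (`2^N x L` matrix; entry `[i, j]` is the
#'   encoded state reached at layer `j` by input `i`), `distinct_counts`
#'   (distinct states per layer), `outputs` (`2^N x H` 0/1 matrix of output
#'   vectors) and `defect_count`.
#'
#' @examples
#' net <- build_lattice(4, 5, a = 0.5, b = 0.5, seed = 1)
#' res <- enumerate_statespace(net, NULL)
#' res$distinct_counts
#' funnel_summary(res)
#' @export
enumerate_statespace <- function(net, ds = NULL, max_n = 20L) {
  stopifnot(inherits(net, "lattice_network"))
  if (net$H > max_n) {
    stop(sprintf(paste("H = %d exceeds the enumeration budget (max_n = %d):",
                       "2^%d inputs would be enumerated. Raise max_n",
                       "explicitly if you really want this."),
                 net$H, max_n, net$H), call. = FALSE)
  }
  mask <- defect_mask(net, ds)
  n <- 2^net$H
  inputs <- 0:(n - 1)
  S0 <- bits_matrix(inputs, net$H)
  layers <- propagate_layers(net, mask, S0)
  pow <- 2^(seq_len(net$H) - 1)
  layer_codes <- vapply(layers, function(m) as.numeric(m %*% pow), numeric(n))
  layer_codes <- matrix(layer_codes, nrow = n, ncol = net$L)
  structure(
    list(N = net$H, L = net$L, inputs = inputs, layer_codes = layer_codes,
         distinct_counts = apply(layer_codes, 2, function(x) length(unique(x))),
         outputs = layers[[net$L]],
         defect_count = if (is.null(ds)) 0L else ds$D),
    class = "statespace_result")
}

# Decode integers 0..2^H-1 into an n x H 0/1 matrix, bit k-1 = pathway k.
bits_matrix <- function(codes, H) {
  m <- matrix(0, length(codes), H)
  for (k in seq_len(H)) {
    m[, k] <- codes %% 2
    codes <- codes %/% 2
  }
  m
}

#' @export
print.statespace_result <- function(x, ...) {
  cat(sprintf("<statespace_result> N=%d inputs (2^N = %d), %d layers, %d defect node(s)\n",
              x$N, length(x$inputs), x$L, x$defect_count))
  cat("  distinct states per layer: ",
      paste(x$distinct_counts, collapse = " "), "\n", sep = "")
  fs <- funnel_summary(x)
  cat(sprintf("  %d phenotype(s); compression %.3f\n",
              fs$n_phenotypes, fs$compression))
  invisible(x)
}

#' Funnelling summary
#'
#' @param res a [statespace_result][enumerate_statespace].
#' @return List with `n_phenotypes` (distinct output states) and
#'   `compression` (`1 - n_phenotypes / 2^N`); compression 0 means the
#'   network is injective (every environment has its own phenotype), values
#'   near 1 mean almost all environments are funnelled onto few phenotypes.
#' @export
funnel_summary <- function(res) {
  stopifnot(inherits(res, "statespace_result"))
  n_ph <- res$distinct_counts[res$L]
  list(n_phenotypes = as.integer(n_ph),
       compression = 1 - n_ph / length(res$inputs))
}

#' Exhaustive healthy-versus-defect comparison
#'
#' Classifies every one of the `2^N` inputs with [classify_step()] applied
#' to the healthy and the defect output: an exhaustive, environment-free
#' version of the Monte-Carlo case statistics (equivalent to sampling inputs
#' uniformly, i.e. input activity 0.5 with every bit redrawn each step).
#'
#' @param res_h state space of the healthy network (empty defect set).
#' @param res_d state space of the defect network on the same topology.
#' @return List with `cases` (one step case per input, in input order) and
#'   `fractions` (exact fraction of inputs per case A/B/C/D).
#' @export
compare_healthy_defect <- function(res_h, res_d) {
  stopifnot(inherits(res_h, "statespace_result"),
            inherits(res_d, "statespace_result"))
  if (res_h$N != res_d$N) stop("mismatched input widths N", call. = FALSE)
  if (res_h$defect_count != 0L) {
    stop("res_h must come from the healthy network (empty defect set)",
         call. = FALSE)
  }
  cases <- classify_steps(res_h$outputs, res_d$outputs)
  tb <- table(factor(cases, levels = STEP_CASES))
  list(cases = cases,
       fractions = stats::setNames(as.numeric(tb) / length(cases), STEP_CASES))
}
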