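# Vectorized feed-forward evaluation. `S` is an n x H 0/1 matrix of layer-1
# states (rows = independent input vectors); returns the list of n x H state
# matrices for layers 1..L. AND nodes require all *realized* incoming edges
# active (a border AND with 2 inputs needs those 2); OR nodes require at
# least one. Defect nodes are forced to 0 in every layer, including layer 1.
propagate_layers <- function(net, mask, S) {
  H <- net$H
  L <- net$L
  n <- nrow(S)
  S <- S * 1 # numeric
  if (any(mask[, 1L])) S[, mask[, 1L]] <- 0
  layers <- vector("list", L)
  layers[[1L]] <- S
  if (L >= 2L) {
    for (j in 2L:L) {
      ep <- net$e_plus[, j - 1L]  # edge (k, j-1) -> (k+1, j)
      em <- net$e_minus[, j - 1L] # edge (k, j-1) -> (k-1, j)
      # weights for the shifted state matrices, indexed by target pathway k
      w_up <- c(0, ep[-H])  # contribution of source k-1 into target k
      w_dn <- c(em[-1L], 0) # contribution of source k+1 into target k
      Sl <- cbind(0, S[, -H, drop = FALSE])  # col k holds state of k-1
      Sr <- cbind(S[, -1L, drop = FALSE], 0) # col k holds state of k+1
      n_act <- S +
        Sl * matrix(w_up, n, H, byrow = TRUE) +
        Sr * matrix(w_dn, n, H, byrow = TRUE)
      n_in <- 1 + w_up + w_dn
      need <- ifelse(net$gates[, j] == "AND", n_in, 1)
      S <- (n_act >= matrix(need, n, H, byrow = TRUE)) * 1
      if (any(mask[, j])) S[, mask[, j]] <- 0
      layers[[j]] <- S
    }
  }
  layers
}

#' Propagate an input vector through the lattice
#'
#' Deterministic single-pass Boolean evaluation, layer by layer (the network
#' is acyclic by construction). Layer-1 states are the input bits, forced to
#' 0 at defect nodes. For `j >= 2` an OR node is active iff at least one
#' incoming neighbour is active and an AND node iff all its realized incoming
#' neighbours are active; a defect node is always 0.
#'
#' @param net a [lattice_network][build_lattice].
#' @param ds a [defect_set][place_defects], or `NULL` for the healthy network.
#' @param input binary (0/1) vector of length `H`.
#' @return An `activity_pattern`: an `H x L` integer 0/1 matrix (rows =
#'   pathways, columns = layers) with attribute `class`.
#'
#' @examples
#' net <- build_lattice(5, 6, a = 0.3, b = 0.5, seed = 1)
#' pat <- propagate(net, NULL, c(1, 0, 1, 1, 0))
#' output_vector(pat)
#' output_strength(output_vector(pat))
#' @export
propagate <- function(net, ds, input) {
  stopifnot(inherits(net, "lattice_network"))
  mask <- defect_mask(net, ds)
  input <- check_input_bits(input, net$H)
  layers <- propagate_layers(net, mask, matrix(input, nrow = 1L))
  pat <- vapply(layers, function(m) as.integer(m[1L, ]), integer(net$H))
  pat <- matrix(pat, nrow = net$H, ncol = net$L)
  class(pat) <- c("activity_pattern", class(pat))
  pat
}

defect_mask <- function(net, ds) {
  if (is.null(ds)) return(matrix(FALSE, net$H, net$L))
  stopifnot(inherits(ds, "defect_set"))
  if (!identical(dim(ds$mask), c(net$H, net$L))) {
    stop("defect set does not match the network dimensions", call. = FALSE)
  }
  ds$mask
}

check_input_bits <- function(input, H) {
  input <- as.numeric(input)
  if (length(input) != H) {
    stop(sprintf("input vector has length %d but the network has H = %d",
                 length(input), H), call. = FALSE)
  }
  if (!all(input %in% c(0, 1))) {
    stop("input vector must be binary (0/1)", call. = FALSE)
  }
  input
}

#' Output vector of an activity pattern
#'
#' The states of the last (phenotype) layer, one bit per pathway.
#'
#' @param pattern an [activity_pattern][propagate].
#' @return Integer 0/1 vector of length `H`.
#' @export
output_vector <- function(pattern) {
  stopifnot(inherits(pattern, "activity_pattern"))
  as.integer(pattern[, ncol(pattern)])
}

#' Output strength
#'
#' The number of active bits in a binary output vector: the model's scalar
#' phenotype readout.
#'
#' @param out binary (0/1) vector.
#' @return Non-negative integer count of ones.
#' @export
output_strength <- function(out) {
  out <- as.numeric(out)
  if (!all(out %in% c(0, 1))) stop("output vector must be binary (0/1)",
                                   call. = FALSE)
  as.integer(sum(out))
}

#' @export
print.activity_pattern <- function(x, ...) {
  cat(sprintf("<activity_pattern> %d pathways x %d layers, %d active nodes\n",
              nrow(x), ncol(x), sum(x)))
  m <- unclass(x)
  dimnames(m) <- list(paste0("k", seq_len(nrow(m))), paste0("j", seq_len(ncol(m))))
  print(m)
  invisible(x)
}
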