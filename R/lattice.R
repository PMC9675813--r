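#' Build a disordered Boolean gate lattice
#'
#' Constructs the model network: `H` parallel directed pathways of length `L`.
#' Every node `(k, j)` (pathway `k`, layer `j`) is connected to its successor
#' `(k, j+1)` within the pathway. In addition each of the two diagonal edges
#' `(k, j) -> (k-1, j+1)` and `(k, j) -> (k+1, j+1)` is drawn independently
#' with the branching probability `b` (edges that would leave the lattice are
#' simply omitted, no wraparound), so every node in layers 2..L has between 1
#' and 3 inputs. Each node is independently assigned a logical AND gate with
#' probability `a`, otherwise a logical OR gate. Layer-1 nodes carry no gate
#' logic: their state is the environment bit (masked if the node is defect).
#'
#' @param H number of parallel pathways (input width).
#' @param L number of layers (pathway length).
#' @param a fraction of AND gates in `[0, 1]`; `1 - a` is the OR fraction.
#' @param b branching probability in `[0, 1]` for each diagonal edge.
#' @param seed integer RNG seed; identical arguments give identical networks.
#'
#' @return An object of class `lattice_network`: a list with elements `H`,
#'   `L`, `a`, `b`, `seed`, `gates` (an `H x L` character matrix of `"AND"` /
#'   `"OR"`), and the diagonal edge indicators `e_plus` (`e_plus[k, j]` is
#'   `TRUE` iff the edge `(k, j) -> (k+1, j+1)` exists) and `e_minus`
#'   (`e_minus[k, j]` for `(k, j) -> (k-1, j+1)`), both `H x (L-1)` logical
#'   matrices.
#'
#' @examples
#' net <- build_lattice(H = 6, L = 8, a = 0.5, b = 0.4, seed = 1)
#' net
#' in_degree(net, k = 3, j = 5)
#' @export
build_lattice <- function(H, L, a, b, seed) {
  H <- check_count(H, "H")
  L <- check_count(L, "L")
  a <- check_fraction(a, "a")
  b <- check_fraction(b, "b")
  seed <- check_count(seed, "seed", min = 0L)

  with_seed(seed, {
    gates <- matrix(ifelse(stats::runif(H * L) < a, "AND", "OR"),
                    nrow = H, ncol = L)
    nb <- max(L - 1L, 0L)
    e_plus <- matrix(stats::runif(H * nb) < b, nrow = H, ncol = nb)
    e_minus <- matrix(stats::runif(H * nb) < b, nrow = H, ncol = nb)
    if (nb > 0L) {
      e_plus[H, ] <- FALSE   # no pathway H+1
      e_minus[1L, ] <- FALSE # no pathway 0
    }
    structure(
      list(H = H, L = L, a = a, b = b, seed = seed,
           gates = gates, e_plus = e_plus, e_minus = e_minus),
      class = "lattice_network")
  })
}

#' @export
print.lattice_network <- function(x, ...) {
  cat(sprintf("<lattice_network> H=%d pathways x L=%d layers\n", x$H, x$L))
  cat(sprintf("  gate ratio a=%.3g (%d AND, %d OR), branching b=%.3g, seed=%d\n",
              x$a, sum(x$gates == "AND"), sum(x$gates == "OR"), x$b, x$seed))
  cat(sprintf("  diagonal edges realized: %d of %d possible\n",
              sum(x$e_plus) + sum(x$e_minus),
              sum(x$e_plus[-x$H, , drop = FALSE] | TRUE) +
                sum(x$e_minus[-1L, , drop = FALSE] | TRUE)))
  invisible(x)
}

check_node <- function(net, k, j) {
  if (!is.numeric(k) || !is.numeric(j) || length(k) != 1L || length(j) != 1L ||
      k < 1 || k > net$H || j < 1 || j > net$L ||
      k != as.integer(k) || j != as.integer(j)) {
    stop(sprintf("node (%s, %s) outside lattice bounds 1..%d x 1..%d",
                 toString(k), toString(j), net$H, net$L), call. = FALSE)
  }
  invisible(c(as.integer(k), as.integer(j)))
}

#' Incoming neighbours of a node
#'
#' All nodes with a directed edge into `(k, j)`. Layer-1 nodes have none:
#' they are fed by the environment.
#'
#' @param net a [lattice_network][build_lattice].
#' @param k,j pathway and layer index of the node.
#' @return A matrix with columns `k`, `j`, one row per incoming neighbour.
#' @export
incoming_neighbors <- function(net, k, j) {
  check_node(net, k, j)
  if (j == 1L) return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("k", "j"))))
  ks <- k
  if (k > 1L && net$e_plus[k - 1L, j - 1L]) ks <- c(ks, k - 1L)
  if (k < net$H && net$e_minus[k + 1L, j - 1L]) ks <- c(ks, k + 1L)
  cbind(k = as.integer(ks), j = rep(j - 1L, length(ks)))
}

#' In-degree of a node
#'
#' @inheritParams incoming_neighbors
#' @return Integer in-degree (0 for layer-1 nodes, 1..3 otherwise).
#' @export
in_degree <- function(net, k, j) {
  nrow(incoming_neighbors(net, k, j))
}

#' Undirected neighbours of a node
#'
#' The union of a node's incoming neighbours and the nodes it feeds into,
#' i.e. adjacency in the realized lattice with edge directions ignored. This
#' is the adjacency used by the Eden growth defect placement.
#'
#' @inheritParams incoming_neighbors
#' @return A matrix with columns `k`, `j`, one row per neighbour.
#' @export
undirected_neighbors <- function(net, k, j) {
  check_node(net, k, j)
  inc <- incoming_neighbors(net, k, j)
  out_k <- integer(0)
  if (j < net$L) {
    out_k <- k # straight edge (k, j) -> (k, j+1) always present
    if (k < net$H && net$e_plus[k, j]) out_k <- c(out_k, k + 1L)
    if (k > 1L && net$e_minus[k, j]) out_k <- c(out_k, k - 1L)
  }
  out <- cbind(k = as.integer(out_k), j = rep(j + 1L, length(out_k)))
  res <- rbind(inc, out)
  res[order(res[, "j"], res[, "k"]), , drop = FALSE]
}

# All directed edges of the network as a matrix (k, j, k2, j2).
# Straight within-pathway edges first, then realized diagonals.
edge_list <- function(net) {
  H <- net$H; L <- net$L
  if (L == 1L) {
    return(matrix(integer(0), ncol = 4,
                  dimnames = list(NULL, c("k", "j", "k2", "j2"))))
  }
  straight <- cbind(k = rep(seq_len(H), L - 1L),
                    j = rep(seq_len(L - 1L), each = H))
  straight <- cbind(straight, k2 = straight[, 1L], j2 = straight[, 2L] + 1L)
  wp <- which(net$e_plus, arr.ind = TRUE)
  plus <- cbind(k = wp[, 1L], j = wp[, 2L], k2 = wp[, 1L] + 1L, j2 = wp[, 2L] + 1L)
  wm <- which(net$e_minus, arr.ind = TRUE)
  minus <- cbind(k = wm[, 1L], j = wm[, 2L], k2 = wm[, 1L] - 1L, j2 = wm[, 2L] + 1L)
  edges <- rbind(straight, plus, minus)
  colnames(edges) <- c("k", "j", "k2", "j2")
  edges[order(edges[, "j"], edges[, "k"], edges[, "k2"]), , drop = FALSE]
}

# Map (k, j) pairs to a single integer node id and back (column-major by layer).
node_id <- function(net, k, j) (j - 1L) * net$H + k
node_kj <- function(net, id) {
  cbind(k = (id - 1L) %% net$H + 1L, j = (id - 1L) %/% net$H + 1L)
}
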