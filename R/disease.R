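#' Place loss-of-function (disease) nodes by Eden growth with teleportation
#'
#' Selects the `D` defect nodes of a disease genotype. The first node is
#' drawn uniformly at random. Each further node is placed by one of two
#' moves: with probability `d` the *current cluster* grows, deactivating a
#' uniformly chosen non-defect node adjacent (in the undirected realized
#' lattice) to the most recently nucleated cluster; otherwise a uniformly
#' chosen non-defect node anywhere is deactivated and becomes the nucleus of
#' a new current cluster (teleportation). If growth is drawn but the current
#' cluster has no free neighbour, the placement falls back to teleportation
#' and `teleport_fallbacks` is incremented, so callers can condition on
#' pure-growth realizations. `d = 1` concentrates all defects in one
#' connected cluster (absent fallbacks); `d = 0` scatters them uniformly.
#'
#' @param net a [lattice_network][build_lattice].
#' @param D number of defect nodes, `0 <= D <= H * L`.
#' @param d clustering parameter in `[0, 1]`.
#' @param seed integer RNG seed.
#'
#' @return An object of class `defect_set`: list with `nodes` (matrix with
#'   columns `k`, `j`, one row per defect node, in placement order), `D`,
#'   `d`, `seed`, `teleport_fallbacks`, and `mask` (`H x L` logical matrix of
#'   defect positions).
#'
#' @examples
#' net <- build_lattice(10, 10, a = 0.5, b = 0.5, seed = 1)
#' ds <- place_defects(net, D = 6, d = 1, seed = 2)
#' ds
#' count_clusters(ds, net)
#' average_location(ds, net)
#' @export
place_defects <- function(net, D, d, seed) {
  stopifnot(inherits(net, "lattice_network"))
  D <- check_count(D, "D", min = 0L)
  d <- check_fraction(d, "d")
  seed <- check_count(seed, "seed", min = 0L)
  n_nodes <- net$H * net$L
  if (D > n_nodes) {
    stop(sprintf("D = %d exceeds the number of lattice nodes (%d)", D, n_nodes),
         call. = FALSE)
  }

  mask <- matrix(FALSE, net$H, net$L)
  ids <- integer(0)
  fallbacks <- 0L

  with_seed(seed, {
    if (D >= 1L) {
      first <- sample.int(n_nodes, 1L)
      ids <- first
      mask[first] <- TRUE
      cluster <- first # the current cluster: the most recently nucleated one
      if (D >= 2L) {
        for (i in 2L:D) {
          grow <- stats::runif(1L) < d
          placed <- NA_integer_
          if (grow) {
            cand <- cluster_frontier(net, cluster, mask)
            if (length(cand) > 0L) {
              placed <- cand[sample.int(length(cand), 1L)]
              cluster <- c(cluster, placed)
            } else {
              fallbacks <- fallbacks + 1L
              grow <- FALSE
            }
          }
          if (!grow) {
            free <- which(!mask)
            placed <- free[sample.int(length(free), 1L)]
            cluster <- placed # new nucleus
          }
          ids <- c(ids, placed)
          mask[placed] <- TRUE
        }
      }
    }
  })

  structure(
    list(nodes = node_kj(net, ids), D = D, d = d, seed = seed,
         teleport_fallbacks = fallbacks, mask = mask),
    class = "defect_set")
}

# Non-defect nodes adjacent (undirected) to any node of `cluster` (node ids).
cluster_frontier <- function(net, cluster, mask) {
  kj <- node_kj(net, cluster)
  nb <- unique(do.call(rbind, lapply(seq_along(cluster), function(i) {
    undirected_neighbors(net, kj[i, "k"], kj[i, "j"])
  })))
  if (is.null(nb) || nrow(nb) == 0L) return(integer(0))
  ids <- node_id(net, nb[, "k"], nb[, "j"])
  unique(ids[!mask[ids]])
}

#' @export
print.defect_set <- function(x, ...) {
  cat(sprintf("<defect_set> D=%d nodes, clustering d=%.3g, seed=%d\n",
              x$D, x$d, x$seed))
  if (x$teleport_fallbacks > 0L) {
    cat(sprintf("  %d forced teleport(s): growth had no free neighbour\n",
                x$teleport_fallbacks))
  }
  if (x$D > 0L) {
    cat("  nodes (k, j): ",
        paste(sprintf("(%d,%d)", x$nodes[, "k"], x$nodes[, "j"]),
              collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

# Empty defect set for a network (the healthy genotype).
empty_defects <- function(net) {
  structure(
    list(nodes = matrix(integer(0), ncol = 2, dimnames = list(NULL, c("k", "j"))),
         D = 0L, d = 0, seed = NA_integer_, teleport_fallbacks = 0L,
         mask = matrix(FALSE, net$H, net$L)),
    class = "defect_set")
}

#' Average location of the genetic damage
#'
#' The mean over defect nodes of `j / L`: the statistic lambda. Values near 1
#' mean the damage sits close to the output (phenotype) layer, values near
#' `1/L` close to the input (environment) layer.
#'
#' @param ds a [defect_set][place_defects] with at least one node.
#' @param net the host [lattice_network][build_lattice].
#' @return The average location, a number in `(0, 1]`.
#' @export
average_location <- function(ds, net) {
  stopifnot(inherits(ds, "defect_set"), inherits(net, "lattice_network"))
  if (nrow(ds$nodes) == 0L) {
    stop("average location is undefined for an empty defect set", call. = FALSE)
  }
  mean(ds$nodes[, "j"]) / net$L
}

#' Number of connected defect clusters
#'
#' Connected components of the defect nodes under undirected lattice
#' adjacency, restricted to defect nodes. A `d = 1` placement without
#' teleport fallbacks has exactly one cluster.
#'
#' @inheritParams average_location
#' @return A positive integer count of components.
#' @export
count_clusters <- function(ds, net) {
  stopifnot(inherits(ds, "defect_set"), inherits(net, "lattice_network"))
  n <- nrow(ds$nodes)
  if (n == 0L) stop("cluster count is undefined for an empty defect set",
                    call. = FALSE)
  ids <- node_id(net, ds$nodes[, "k"], ds$nodes[, "j"])
  in_set <- logical(net$H * net$L)
  in_set[ids] <- TRUE
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    nb <- undirected_neighbors(net, ds$nodes[i, "k"], ds$nodes[i, "j"])
    nb_ids <- node_id(net, nb[, "k"], nb[, "j"])
    nb_ids <- nb_ids[in_set[nb_ids]]
    if (length(nb_ids) == 0L) return(NULL)
    cbind(match(ids[i], ids), match(nb_ids, ids))
  }))
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0L) {
    g <- igraph::add_edges(g, t(edges))
  }
  as.integer(igraph::components(g)$no)
}
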