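# Shared fixtures and independent oracles. The oracles deliberately use the
# slow, obvious formulation (per-node loops, union-find over all pairs) so
# they stay independent of the vectorized implementation they check.

# Hand-built 3x3 fixture: all OR gates except an AND at (2, 3); straight
# pathway edges plus the two diagonals (1,1)->(2,2) and (3,2)->(2,3).
make_fixture_net <- function() {
  e_plus <- matrix(FALSE, 3, 2)
  e_minus <- matrix(FALSE, 3, 2)
  e_plus[1, 1] <- TRUE  # (1,1) -> (2,2)
  e_minus[3, 2] <- TRUE # (3,2) -> (2,3)
  gates <- matrix("OR", 3, 3)
  gates[2, 3] <- "AND"
  structure(
    list(H = 3L, L = 3L, a = NA_real_, b = NA_real_, seed = 0L,
         gates = gates, e_plus = e_plus, e_minus = e_minus),
    class = "lattice_network")
}

# Defect set at explicit (k, j) positions, bypassing the Eden process.
manual_defects <- function(net, kj) {
  kj <- matrix(as.integer(kj), ncol = 2, dimnames = list(NULL, c("k", "j")))
  mask <- matrix(FALSE, net$H, net$L)
  if (nrow(kj) > 0) mask[kj] <- TRUE
  structure(
    list(nodes = kj, D = nrow(kj), d = NA_real_, seed = NA_integer_,
         teleport_fallbacks = 0L, mask = mask),
    class = "defect_set")
}

# Naive per-node truth-table evaluation: loops over nodes, reads gates and
# incoming neighbours one at a time.
oracle_propagate <- function(net, ds, input) {
  mask <- if (is.null(ds)) matrix(FALSE, net$H, net$L) else ds$mask
  s <- matrix(0L, net$H, net$L)
  for (k in seq_len(net$H)) {
    s[k, 1] <- if (mask[k, 1]) 0L else as.integer(input[k])
  }
  if (net$L >= 2) {
    for (j in 2:net$L) {
      for (k in seq_len(net$H)) {
        nb <- incoming_neighbors(net, k, j)
        vals <- s[cbind(nb[, "k"], nb[, "j"])]
        act <- if (net$gates[k, j] == "AND") all(vals == 1L) else any(vals == 1L)
        s[k, j] <- if (mask[k, j]) 0L else as.integer(act)
      }
    }
  }
  s
}

# Union-find over all defect-node pairs: component count oracle.
oracle_count_clusters <- function(ds, net) {
  n <- nrow(ds$nodes)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  adjacent <- function(i, j) {
    nb <- undirected_neighbors(net, ds$nodes[i, "k"], ds$nodes[i, "j"])
    any(nb[, "k"] == ds$nodes[j, "k"] & nb[, "j"] == ds$nodes[j, "j"])
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && adjacent(i, j)) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  length(unique(vapply(seq_len(n), find, 1L)))
}

# A random lattice with dimensions and parameters drawn under the given seed.
rand_net <- function(seed, H = NULL, L = NULL, a = NULL, b = NULL) {
  set.seed(seed)
  build_lattice(
    H = if (is.null(H)) sample(3:10, 1) else H,
    L = if (is.null(L)) sample(3:10, 1) else L,
    a = if (is.null(a)) runif(1) else a,
    b = if (is.null(b)) runif(1) else b,
    seed = sample.int(1e6, 1))
}

rand_input <- function(H, p = 0.5) as.integer(runif(H) < p)
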