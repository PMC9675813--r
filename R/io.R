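#' Serialize a network (and optionally its defect set) to JSON
#'
#' Writes `{H, L, a, b, seed, gates: [[k, j, "AND"|"OR"], ...],
#' edges: [[k, j, k2, j2], ...]}` plus, when `ds` is given, a `defects`
#' object `{D, d, seed, teleport_fallbacks, nodes: [[k, j], ...]}`.
#' Coordinates are 1-based, matching the `(k, j)` convention throughout.
#'
#' @param net a [lattice_network][build_lattice].
#' @param path output path.
#' @param ds optional [defect_set][place_defects].
#' @return `path`, invisibly.
#' @export
write_network_json <- function(net, path, ds = NULL) {
  stopifnot(inherits(net, "lattice_network"))
  gk <- expand.grid(k = seq_len(net$H), j = seq_len(net$L),
                    KEEP.OUT.ATTRS = FALSE)
  gates <- Map(function(k, j) list(k, j, net$gates[k, j]), gk$k, gk$j)
  ed <- edge_list(net)
  edges <- lapply(seq_len(nrow(ed)), function(i) as.list(unname(ed[i, ])))
  doc <- list(H = net$H, L = net$L, a = net$a, b = net$b, seed = net$seed,
              gates = gates, edges = edges)
  if (!is.null(ds)) {
    stopifnot(inherits(ds, "defect_set"))
    nodes <- lapply(seq_len(nrow(ds$nodes)), function(i) {
      list(ds$nodes[i, "k"], ds$nodes[i, "j"])
    })
    doc$defects <- list(D = ds$D, d = ds$d, seed = ds$seed,
                        teleport_fallbacks = ds$teleport_fallbacks,
                        nodes = nodes)
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a network (and defect set) back from JSON
#'
#' Inverse of [write_network_json()]: the reconstructed objects are
#' identical to the serialized ones.
#'
#' @param path path to a network JSON file.
#' @return List with elements `net` (a `lattice_network`) and `ds` (a
#'   `defect_set`, or `NULL` if none was serialized).
#' @export
read_network_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  H <- as.integer(doc$H); L <- as.integer(doc$L)
  gates <- matrix(NA_character_, H, L)
  gm <- doc$gates # simplifies to an n x 3 character matrix [k, j, gate]
  gates[cbind(as.integer(gm[, 1]), as.integer(gm[, 2]))] <- as.character(gm[, 3])
  nb <- max(L - 1L, 0L)
  e_plus <- matrix(FALSE, H, nb)
  e_minus <- matrix(FALSE, H, nb)
  ed <- doc$edges # n x 4 matrix [k, j, k2, j2]
  if (length(ed) > 0L) {
    k <- as.integer(ed[, 1]); j <- as.integer(ed[, 2])
    k2 <- as.integer(ed[, 3]); j2 <- as.integer(ed[, 4])
    stopifnot(all(j2 == j + 1L), all(abs(k2 - k) <= 1L))
    up <- k2 == k + 1L
    dn <- k2 == k - 1L
    e_plus[cbind(k[up], j[up])] <- TRUE
    e_minus[cbind(k[dn], j[dn])] <- TRUE
  }
  net <- structure(
    list(H = H, L = L, a = as.numeric(doc$a), b = as.numeric(doc$b),
         seed = as.integer(doc$seed), gates = gates,
         e_plus = e_plus, e_minus = e_minus),
    class = "lattice_network")
  ds <- NULL
  if (!is.null(doc$defects)) {
    dd <- doc$defects
    nodes <- dd$nodes # n x 2 matrix [k, j]
    nodes <- if (length(nodes) == 0L) {
      matrix(integer(0), ncol = 2)
    } else {
      cbind(as.integer(nodes[, 1]), as.integer(nodes[, 2]))
    }
    colnames(nodes) <- c("k", "j")
    mask <- matrix(FALSE, H, L)
    if (nrow(nodes) > 0L) mask[nodes] <- TRUE
    ds <- structure(
      list(nodes = nodes, D = as.integer(dd$D), d = as.numeric(dd$d),
           seed = as.integer(dd$seed),
           teleport_fallbacks = as.integer(dd$teleport_fallbacks),
           mask = mask),
      class = "defect_set")
  }
  list(net = net, ds = ds)
}

# Write a data.frame as CSV preceded by '#' comment lines echoing the
# parameters and seeds, so every output file can regenerate itself.
write_csv_with_header <- function(df, path, header) {
  lines <- sprintf("# %s=%s", names(header),
                   vapply(header, function(v) paste(format(v, digits = 15),
                                                    collapse = ","), ""))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(lines, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a CSV written by the package's CLI
#'
#' Skips the `# key=value` provenance header and returns the data plus the
#' parsed header.
#'
#' @param path path to a CSV written by [run_cli()].
#' @return data.frame with attribute `header` (named character vector).
#' @export
read_csv_with_header <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  kv <- sub("^# ", "", lines[hdr])
  header <- stats::setNames(sub("^[^=]*=", "", kv), sub("=.*$", "", kv))
  df <- utils::read.csv(text = lines[-hdr], stringsAsFactors = FALSE)
  attr(df, "header") <- header
  df
}
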