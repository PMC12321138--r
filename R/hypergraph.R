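#' Construct a hypergraph from a list of hyperedges
#'
#' A hypergraph is a set of nodes together with hyperedges, each of which
#' joins two or more nodes. The order `g_e` of a hyperedge is the number of
#' nodes it contains; the hyperdegree `k_i` of a node is the number of
#' hyperedges it belongs to. `hypergraph()` validates and freezes the
#' incidence structure: every hyperedge must have order at least 2 with no
#' repeated member, every node must belong to at least one hyperedge, and the
#' bipartite node-hyperedge incidence graph must be connected (fixation of a
#' single mutant is ill-defined across disconnected components).
#'
#' Hyperedges are sets: membership is binary and member order is
#' irrelevant. Duplicate hyperedges (two hyperedges with identical node
#' sets) are permitted and count as distinct hyperedges in all statistics.
#'
#' @param edges list of character or integer vectors, one hyperedge each.
#'   Elements are node labels; integers are treated as labels, not indices.
#' @param labels optional character vector fixing the node order. Defaults to
#'   first-appearance order across `edges`.
#' @return An object of class `hypergraph` with fields `edges` (list of
#'   integer index vectors, 1-based, sorted), `labels` (character), `N`, `E`.
#' @examples
#' H <- hypergraph(list(c(1, 2, 3), c(3, 4)))
#' hyperdegrees(H)
#' @export
hypergraph <- function(edges, labels = NULL) {
  if (!is.list(edges) || length(edges) == 0) {
    stop("`edges` must be a non-empty list of hyperedges", call. = FALSE)
  }
  edges_chr <- lapply(edges, function(e) as.character(e))
  if (is.null(labels)) {
    labels <- unique(unlist(edges_chr, use.names = FALSE))
  } else {
    labels <- as.character(labels)
    if (anyDuplicated(labels)) stop("duplicate node labels", call. = FALSE)
    unseen <- setdiff(unique(unlist(edges_chr)), labels)
    if (length(unseen) > 0) {
      stop("hyperedges mention labels not in `labels`: ",
           paste(utils::head(unseen, 5), collapse = ", "), call. = FALSE)
    }
  }
  idx_edges <- lapply(seq_along(edges_chr), function(a) {
    e <- edges_chr[[a]]
    if (length(e) < 2) {
      stop("hyperedge ", a, " has order ", length(e),
           "; every hyperedge must contain at least 2 nodes", call. = FALSE)
    }
    if (anyDuplicated(e)) {
      stop("hyperedge ", a, " contains a repeated node (",
           e[duplicated(e)][1], ")", call. = FALSE)
    }
    sort(match(e, labels))
  })
  H <- structure(
    list(edges = idx_edges, labels = labels,
         N = length(labels), E = length(idx_edges)),
    class = "hypergraph"
  )
  k <- hyperdegrees(H)
  if (any(k == 0)) {
    stop("isolated node(s): ", paste(utils::head(labels[k == 0], 5),
                                     collapse = ", "), call. = FALSE)
  }
  if (!incidence_connected(H)) {
    stop("the node-hyperedge incidence graph is disconnected", call. = FALSE)
  }
  H
}

# Connectivity of the bipartite node-hyperedge incidence graph.
incidence_connected <- function(H) {
  el <- cbind(
    rep(seq_len(H$E) + H$N, lengths(H$edges)),
    unlist(H$edges, use.names = FALSE)
  )
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  n_present <- H$N + H$E
  igraph::vcount(g) >= n_present &&
    igraph::components(g)$no == 1
}

#' @export
print.hypergraph <- function(x, ...) {
  k <- hyperdegrees(x)
  g <- hyperedge_orders(x)
  cat("A hypergraph with", x$N, "nodes and", x$E, "hyperedges\n")
  cat("  hyperdegree: ", paste0("[", min(k), ", ", max(k), "]"),
      " mean ", format(mean(k), digits = 4), "\n", sep = "")
  cat("  order:       ", paste0("[", min(g), ", ", max(g), "]"),
      " mean ", format(mean(g), digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
format.hypergraph <- function(x, ...) {
  paste0("<hypergraph: N=", x$N, ", E=", x$E, ">")
}

#' Hyperdegrees and hyperedge orders
#'
#' The hyperdegree `k_i` counts the hyperedges containing node `i`
#' (`k_i = sum_e b(i,e)`); the order `g_e` counts the nodes in hyperedge `e`
#' (`g_e = sum_i b(i,e)`), where `b(i,e)` is the binary incidence. The two
#' sequences obey the handshake identity `sum_i k_i = sum_e g_e`.
#'
#' @param H a [hypergraph()]
#' @return `hyperdegrees()`: an integer vector of length `N` named by node
#'   label; `hyperedge_orders()`: an integer vector of length `E`.
#' @export
hyperdegrees <- function(H) {
  stopifnot(inherits(H, "hypergraph"))
  k <- tabulate(unlist(H$edges, use.names = FALSE), nbins = H$N)
  names(k) <- H$labels
  k
}

#' @rdname hyperdegrees
#' @export
hyperedge_orders <- function(H) {
  stopifnot(inherits(H, "hypergraph"))
  lengths(H$edges)
}

#' Sparse incidence matrix
#'
#' @param H a [hypergraph()]
#' @return An `N x E` sparse 0/1 matrix `B` with `B[i, e] = b(i, e)`.
#' @export
incidence_matrix <- function(H) {
  stopifnot(inherits(H, "hypergraph"))
  Matrix::sparseMatrix(
    i = unlist(H$edges, use.names = FALSE),
    j = rep(seq_len(H$E), lengths(H$edges)),
    x = 1, dims = c(H$N, H$E),
    dimnames = list(H$labels, NULL)
  )
}

#' Shared-hyperedge counts for all node pairs
#'
#' `m[i, v] = sum_e b(i,e) b(v,e)` counts the hyperedges containing both `i`
#' and `v`. The matrix is symmetric with `m[i, i] = k_i`.
#'
#' @param H a [hypergraph()]
#' @return A dense `N x N` integer-valued matrix.
#' @export
shared_edge_counts <- function(H) {
  B <- incidence_matrix(H)
  as.matrix(Matrix::tcrossprod(B))
}

#' Is every node's hyperdegree and every hyperedge's order constant?
#'
#' @param H a [hypergraph()]
#' @return `TRUE` for homogeneous hypergraphs (constant `k` and constant `g`).
#' @export
is_homogeneous <- function(H) {
  k <- hyperdegrees(H)
  g <- hyperedge_orders(H)
  length(unique(k)) == 1L && length(unique(g)) == 1L
}

#' Read a hypergraph from a hyperedge-list file
#'
#' One hyperedge per line, whitespace-separated node labels; `#` starts a
#' comment; blank lines are ignored. Node labels are arbitrary strings and
#' are mapped to internal indices in first-appearance order.
#'
#' @param path path to a hyperedge-list text file
#' @return a validated [hypergraph()]
#' @export
read_hypergraph <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("no hyperedges in ", path, call. = FALSE)
  hypergraph(strsplit(lines, "[[:space:]]+"))
}

#' Write a hypergraph as a hyperedge-list file
#'
#' Inverse of [read_hypergraph()]: one hyperedge per line in input order,
#' node labels separated by single spaces. `read_hypergraph(write_hypergraph(H))`
#' reproduces the incidence structure exactly.
#'
#' @param H a [hypergraph()]
#' @param path output file path
#' @return `path`, invisibly.
#' @export
write_hypergraph <- function(H, path) {
  stopifnot(inherits(H, "hypergraph"))
  lines <- vapply(H$edges, function(e) paste(H$labels[e], collapse = " "), "")
  writeLines(lines, path)
  invisible(path)
}

#' Export the incidence as a node-hyperedge table
#'
#' @param H a [hypergraph()]
#' @return A tibble with one row per membership: `node` (label),
#'   `hyperedge` (1-based hyperedge id in input order).
#' @export
incidence_table <- function(H) {
  stopifnot(inherits(H, "hypergraph"))
  tibble::tibble(
    node = H$labels[unlist(H$edges, use.names = FALSE)],
    hyperedge = rep(seq_len(H$E), lengths(H$edges))
  )
}
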