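#' The nine-node worked-example hypergraph
#'
#' The small fixture used throughout the documentation and tests: nine nodes
#' labelled 1-9 and four hyperedges \{1,2,3,4,5\}, \{4,5,7,8\}, \{6,7\},
#' \{5,8,9\}. Node 5 has hyperdegree 3; the second hyperedge has order 4;
#' the degree and order sequences both sum to 14.
#'
#' @return a [hypergraph()] with `N = 9`, `E = 4`
#' @export
hg_example9 <- function() {
  hypergraph(list(c(1, 2, 3, 4, 5), c(4, 5, 7, 8), c(6, 7), c(5, 8, 9)),
             labels = as.character(1:9))
}

#' Homogeneous hypergraph with minimal (weak) overlap
#'
#' Generates a connected hypergraph with constant hyperdegree `k`, constant
#' order `g`, and every pair of distinct hyperedges sharing at most one node,
#' so that the rescaled overlap strength attains its minimum `1/g` and
#' `theta_tilde = 0`.
#'
#' Three constructions are used:
#' * `k = 2`: sample a connected simple `g`-regular graph on `n_edges`
#'   hyperedge-vertices and place one node on each graph edge; each
#'   hyperedge is the set of nodes on its incident graph edges.
#'   `N = n_edges * g / 2`.
#' * `k = g`: deterministic cyclic construction; hyperedges are the
#'   translates `m + B (mod N)` of a Sidon set `B` of size `g` (all pairwise
#'   differences distinct mod `N`), which guarantees overlaps of at most one
#'   node. `N = n_edges`.
#' * otherwise: `(k, g)`-biregular bipartite stub matching with bounded
#'   rewiring until no two hyperedges share two or more nodes.
#'
#' @param k constant hyperdegree, `>= 2`
#' @param g constant order, `>= 2`
#' @param n_edges number of hyperedges
#' @param seed optional RNG seed for the randomized constructions
#' @param max_tries attempts for the rewiring construction
#' @return a [hypergraph()] with `rescaled_overlap(H) == 1/g`
#' @examples
#' H <- hg_homogeneous_weak(2, 4, 20, seed = 1)
#' rescaled_overlap(H) # 1/4
#' @export
hg_homogeneous_weak <- function(k, g, n_edges, seed = NULL, max_tries = 200) {
  stopifnot(k >= 2, g >= 2, n_edges >= 2)
  if (!is.null(seed)) set.seed(seed)
  if (k == 2) {
    if ((n_edges * g) %% 2 != 0) {
      stop("n_edges * g must be even for the k = 2 construction", call. = FALSE)
    }
    gr <- igraph::sample_degseq(rep(g, n_edges), method = "vl")
    el <- igraph::as_edgelist(gr)
    # node per graph edge; hyperedge e collects nodes on edges incident to e
    edges <- lapply(seq_len(n_edges), function(e) {
      which(el[, 1] == e | el[, 2] == e)
    })
    return(hypergraph(edges, labels = as.character(seq_len(nrow(el)))))
  }
  if (k == g) {
    N <- n_edges
    B <- sidon_set(g, N)
    edges <- lapply(seq_len(N), function(m) ((m - 1 + B) %% N) + 1)
    return(hypergraph(edges, labels = as.character(seq_len(N))))
  }
  hg_biregular_weak(k, g, n_edges, max_tries = max_tries)
}

# Greedy Sidon set of size g in Z_N: all pairwise differences distinct mod N.
sidon_set <- function(g, N) {
  B <- 0L
  used <- rep(FALSE, N) # used[d+1] marks difference d taken (both signs)
  cand <- 1L
  while (length(B) < g) {
    if (cand >= N) {
      stop("population too small for a weak-overlap window construction ",
           "with order ", g, call. = FALSE)
    }
    d_new <- c((cand - B) %% N, (B - cand) %% N)
    if (!any(used[d_new + 1L]) && !anyDuplicated(d_new)) {
      B <- c(B, cand)
      used[d_new + 1L] <- TRUE
    }
    cand <- cand + 1L
  }
  B
}

# (k, g)-biregular incidence with all pairwise hyperedge overlaps <= 1,
# by stub matching followed by score-guided swap repair (hill climbing on
# the number of excess shared nodes, with plateau moves to escape local
# minima). Tightly constrained parameter sets (e.g. the extremal case
# where every pair of hyperedges must share exactly one node) may need
# many restarts or be genuinely infeasible.
hg_biregular_weak <- function(k, g, n_edges, max_tries = 200) {
  if ((n_edges * g) %% k != 0) {
    stop("n_edges * g must be divisible by k", call. = FALSE)
  }
  N <- n_edges * g / k
  if (g > N) stop("order exceeds node count", call. = FALSE)
  # counting bound: each node contributes k(k-1) ordered pairs of adjacent
  # hyperedges sharing it; with all overlaps <= 1 these pairs are distinct,
  # so N k (k-1) <= E (E-1) is necessary for a weak-overlap construction
  if (N * k * (k - 1) > n_edges * (n_edges - 1)) {
    stop("weak overlap infeasible: N k (k - 1) = ", N * k * (k - 1),
         " exceeds the ", n_edges * (n_edges - 1),
         " available ordered hyperedge pairs; increase n_edges",
         call. = FALSE)
  }
  for (try in seq_len(max_tries)) {
    memb <- matrix(sample(rep(seq_len(N), each = k)), nrow = g)
    memb <- repair_biregular(memb, N)
    if (is.null(memb)) next
    H <- try(hypergraph(lapply(seq_len(n_edges), function(j) memb[, j]),
                        labels = as.character(seq_len(N))), silent = TRUE)
    if (!inherits(H, "try-error")) return(H)
  }
  stop("could not construct a weak-overlap (", k, ", ", g,
       ")-biregular hypergraph after ", max_tries, " attempts", call. = FALSE)
}

# Swap memberships between hyperedges until no node repeats within a
# hyperedge and no two hyperedges share more than one node. Returns the
# repaired g x E membership matrix, or NULL if this start got stuck.
repair_biregular <- function(memb, N, max_passes = NULL) {
  g <- nrow(memb); E <- ncol(memb)
  if (is.null(max_passes)) max_passes <- 200L + 40L * E
  B <- matrix(0L, N, E)
  for (j in seq_len(E)) {
    tab <- tabulate(memb[, j], nbins = N)
    B[, j] <- tab
  }
  # score of column j against all others given current B
  col_score <- function(j) {
    ov <- as.vector(crossprod(B[, j], B))
    ov[j] <- 0
    sum(pmax(B[, j] - 1L, 0L)) * g + sum(pmax(ov - 1, 0))
  }
  apply_swap <- function(r1, j, r2, j2) {
    v <- memb[r1, j]; w <- memb[r2, j2]
    memb[r1, j] <<- w; memb[r2, j2] <<- v
    B[v, j] <<- B[v, j] - 1L; B[w, j] <<- B[w, j] + 1L
    B[w, j2] <<- B[w, j2] - 1L; B[v, j2] <<- B[v, j2] + 1L
  }
  for (pass in seq_len(max_passes)) {
    dup_excess <- pmax(B - 1L, 0L)
    ov_all <- crossprod(B)
    diag(ov_all) <- 0
    total <- sum(dup_excess) * g + sum(pmax(ov_all - 1, 0)) / 2
    if (total == 0) {
      return(memb)
    }
    # locate one violating membership (duplicate first, then shared pair)
    if (sum(dup_excess) > 0) {
      j <- which(colSums(dup_excess) > 0)[1]
      v <- which(B[, j] > 1)[1]
      r1 <- which(memb[, j] == v)[1]
    } else {
      bad <- which(ov_all >= 2, arr.ind = TRUE)
      pick <- bad[sample.int(nrow(bad), 1), ]
      j <- pick[1]
      shared <- intersect(memb[, j], memb[, pick[2]])
      v <- shared[sample.int(length(shared), 1)]
      r1 <- which(memb[, j] == v)[1]
    }
    # try random swap partners; accept score-improving (or rarely equal)
    before <- NULL
    improved <- FALSE
    for (cand in seq_len(40L)) {
      j2 <- sample.int(E, 1)
      if (j2 == j) next
      r2 <- sample.int(g, 1)
      if (is.null(before)) before <- col_score(j) + col_score(j2)
      else before <- col_score(j) + col_score(j2)
      apply_swap(r1, j, r2, j2)
      after <- col_score(j) + col_score(j2)
      if (after < before || (after == before && stats::runif(1) < 0.15)) {
        improved <- TRUE
        break
      }
      apply_swap(r1, j, r2, j2) # revert
    }
    if (!improved) {
      # shake: random swap to escape, counted against the pass budget
      j2 <- sample.int(E, 1)
      if (j2 != j) apply_swap(r1, j, sample.int(g, 1), j2)
    }
  }
  NULL
}

#' Ring of hyperedges with controlled consecutive overlap
#'
#' A cyclic chain of `n_edges` order-`g` hyperedges in which consecutive
#' hyperedges share exactly `overlap` nodes and non-consecutive hyperedges
#' are disjoint. Requires `g = 2 * overlap` so that every node lies in
#' exactly two hyperedges (constant hyperdegree 2). `N = n_edges * overlap`.
#' With `g = 4`, `overlap = 2` the rescaled overlap strength is `1/2`
#' (the moderate-overlap family).
#'
#' @param g hyperedge order (must equal `2 * overlap`)
#' @param overlap nodes shared by consecutive hyperedges
#' @param n_edges number of hyperedges in the ring, `>= 3`
#' @return a [hypergraph()]
#' @export
hg_ring_overlap <- function(g = 4, overlap = g / 2, n_edges) {
  stopifnot(overlap >= 1, n_edges >= 3)
  if (g != 2 * overlap) {
    stop("the ring construction requires g = 2 * overlap so that every ",
         "node has hyperdegree exactly 2", call. = FALSE)
  }
  # block b of `overlap` nodes is shared by hyperedges b and b+1 (cyclic)
  blocks <- split(seq_len(n_edges * overlap),
                  rep(seq_len(n_edges), each = overlap))
  edges <- lapply(seq_len(n_edges), function(e) {
    prev <- if (e == 1) n_edges else e - 1
    c(blocks[[prev]], blocks[[e]])
  })
  hypergraph(edges, labels = as.character(seq_len(n_edges * overlap)))
}

#' Closed chain of strongly overlapping hyperedge dimers
#'
#' `n_dimers` pairs of order-4 hyperedges arranged on a cycle. The two
#' hyperedges within a pair share 3 nodes; consecutive pairs are linked by a
#' single shared node. Every node has hyperdegree 2, `N = 4 * n_dimers`, and
#' the rescaled overlap strength is `5/8` (the strong-overlap `k = 2`,
#' `g = 4` family: each hyperedge contributes `3^2 + 1^2 = 10` to the
#' ordered overlap-square sum).
#'
#' @param n_dimers number of hyperedge pairs, `>= 2`
#' @return a [hypergraph()]
#' @export
hg_dimer_chain <- function(n_dimers) {
  stopifnot(n_dimers >= 2)
  edges <- vector("list", 2 * n_dimers)
  for (d in seq_len(n_dimers)) {
    core <- (d - 1) * 4 + 1:3
    link_right <- (d - 1) * 4 + 4
    link_left <- if (d == 1) n_dimers * 4 else (d - 2) * 4 + 4
    edges[[2 * d - 1]] <- c(core, link_left)   # A_d
    edges[[2 * d]] <- c(core, link_right)      # B_d
  }
  hypergraph(edges, labels = as.character(seq_len(4 * n_dimers)))
}

#' Ring of sliding windows
#'
#' Hyperedges are all `N` cyclic windows `{v_m, ..., v_{m+g-1}}` of `g`
#' consecutive nodes on a ring of `N` nodes, so every node has hyperdegree
#' `g`. For `g = 3` the rescaled overlap strength is `5/9` (the strong
#' `k = 3, g = 3` family: each window shares 2 nodes with each neighbouring
#' window and 1 node with each next-nearest window).
#'
#' @param N ring size, `>= 2 * g`
#' @param g window width (hyperedge order)
#' @return a [hypergraph()] with constant `k = g`
#' @export
hg_window_ring <- function(N, g = 3) {
  stopifnot(g >= 2)
  if (N < 2 * g) stop("need N >= 2 * g for distinct windows", call. = FALSE)
  edges <- lapply(seq_len(N), function(m) ((m - 1 + 0:(g - 1)) %% N) + 1)
  hypergraph(edges, labels = as.character(seq_len(N)))
}

#' Configuration-model hypergraph with prescribed sequences
#'
#' Samples a hypergraph whose hyperdegree sequence equals
#' `hyperdegree_sequence` and whose order sequence equals `order_sequence`,
#' by uniform stub matching on the bipartite node-hyperedge incidence.
#' A node matched twice into the same hyperedge is repaired by swapping one
#' of its stubs with a random stub of another hyperedge (rather than
#' rejecting the whole sample, which is hopeless for heavy-tailed
#' sequences); disconnected samples are resampled.
#'
#' @param hyperdegree_sequence integer vector (length `N`), all `>= 1`
#' @param order_sequence integer vector (length `E`), all `>= 2`; sums must
#'   match `sum(hyperdegree_sequence)`
#' @param seed optional RNG seed
#' @param max_tries resampling attempts for connectivity/repair failures
#' @return a [hypergraph()] realizing both sequences exactly
#' @examples
#' H <- hg_configuration_model(rep(4, 20), rep(4, 20), seed = 1)
#' @export
hg_configuration_model <- function(hyperdegree_sequence, order_sequence,
                                   seed = NULL, max_tries = 200) {
  k_seq <- as.integer(hyperdegree_sequence)
  g_seq <- as.integer(order_sequence)
  if (any(k_seq < 1)) stop("hyperdegrees must be >= 1", call. = FALSE)
  if (any(g_seq < 2)) stop("orders must be >= 2", call. = FALSE)
  if (sum(k_seq) != sum(g_seq)) {
    stop("sum(hyperdegree_sequence) must equal sum(order_sequence) (",
         sum(k_seq), " vs ", sum(g_seq), ")", call. = FALSE)
  }
  N <- length(k_seq)
  if (max(g_seq) > N) stop("an order exceeds the node count", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  E <- length(g_seq)
  edge_of_stub <- rep(seq_len(E), g_seq)
  for (try in seq_len(max_tries)) {
    stubs <- sample(rep(seq_len(N), k_seq))
    # repair duplicate membership by stub swaps
    ok <- TRUE
    for (pass in seq_len(100L + 10L * sum(g_seq))) {
      memb <- split(stubs, edge_of_stub)
      dup_edge <- which(vapply(memb, anyDuplicated, 0L) > 0)
      if (length(dup_edge) == 0) break
      e <- dup_edge[1]
      pos_in_e <- which(edge_of_stub == e)
      d <- pos_in_e[duplicated(stubs[pos_in_e])][1]
      o <- sample(which(edge_of_stub != e), 1)
      # swap only if it does not create a new duplicate
      v_d <- stubs[d]; v_o <- stubs[o]
      e_o <- edge_of_stub[o]
      in_e <- stubs[edge_of_stub == e]
      in_o <- stubs[edge_of_stub == e_o]
      if (v_o %in% in_e || v_d %in% in_o) next
      stubs[d] <- v_o; stubs[o] <- v_d
    }
    memb <- split(stubs, edge_of_stub)
    if (any(vapply(memb, anyDuplicated, 0L) > 0)) next
    H <- try(hypergraph(unname(memb), labels = as.character(seq_len(N))),
             silent = TRUE)
    if (!inherits(H, "try-error")) return(H)
  }
  stop("configuration model failed to produce a valid connected hypergraph ",
       "after ", max_tries, " attempts", call. = FALSE)
}

#' Sample hyperdegree or order sequences
#'
#' Integer sequences for the configuration model: `constant`, `poisson`
#' (shifted so no value falls below the legal minimum), or `powerlaw`
#' (discrete inverse-transform sampling of \eqn{P(x) \propto x^{-\gamma}}).
#' Hyperdegrees have minimum 1; orders have minimum 2 (set `min_value`).
#'
#' @param kind one of `"constant"`, `"poisson"`, `"powerlaw"`
#' @param n sequence length
#' @param value constant value (`kind = "constant"`)
#' @param mean target mean (`kind = "poisson"`)
#' @param exponent power-law exponent `> 1` (`kind = "powerlaw"`)
#' @param min_value legal minimum (1 for hyperdegrees, 2 for orders)
#' @param max_value optional truncation (e.g. the node count for orders)
#' @param seed optional RNG seed
#' @return an integer vector of length `n`
#' @export
sample_sequence <- function(kind = c("constant", "poisson", "powerlaw"),
                            n, value = NULL, mean = NULL, exponent = NULL,
                            min_value = 1, max_value = Inf, seed = NULL) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  x <- switch(kind,
    constant = {
      stopifnot(!is.null(value), value >= min_value)
      rep(as.integer(value), n)
    },
    poisson = {
      stopifnot(!is.null(mean), mean > min_value)
      min_value + stats::rpois(n, mean - min_value)
    },
    powerlaw = {
      stopifnot(!is.null(exponent), exponent > 1)
      u <- stats::runif(n)
      floor(min_value * (1 - u)^(-1 / (exponent - 1)))
    }
  )
  as.integer(pmin(x, max_value))
}

#' Adjust an order sequence so its total matches a hyperdegree sequence
#'
#' The configuration model needs `sum(k) == sum(g)`. Starting from a
#' proposal order sequence, single elements are resampled (or nudged by one
#' within legal bounds) until the totals agree.
#'
#' @param order_sequence proposal integer sequence (minimum 2)
#' @param target required total, typically `sum(hyperdegree_sequence)`
#' @param min_value,max_value legal bounds for an order
#' @return an integer sequence of the same length summing to `target`
#' @export
match_sequence_total <- function(order_sequence, target, min_value = 2,
                                 max_value = Inf) {
  g <- as.integer(order_sequence)
  lo <- length(g) * min_value
  if (target < lo) {
    stop("target total ", target, " infeasible for ", length(g),
         " orders of at least ", min_value, call. = FALSE)
  }
  guard <- 0L
  while (sum(g) != target) {
    i <- sample.int(length(g), 1)
    step <- sign(target - sum(g))
    cand <- g[i] + step
    if (cand >= min_value && cand <= max_value) g[i] <- cand
    guard <- guard + 1L
    if (guard > 1e6) stop("sequence matching did not converge", call. = FALSE)
  }
  g
}
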