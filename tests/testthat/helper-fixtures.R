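# Small hypergraphs used across tests, built in code.

# two overlapping triangles sharing an edge of two nodes: N = 4
hg_bowtie <- function() {
  hypergraph(list(c(1, 2, 3), c(2, 3, 4)))
}

# homogeneous N = 6, k = 2, g = 3 (4 triangles on 6 nodes)
hg_small_homog <- function() {
  hypergraph(list(c(1, 2, 3), c(3, 4, 5), c(5, 6, 1), c(2, 4, 6)))
}

# a single hyperedge of order n
hg_single <- function(n = 4) {
  hypergraph(list(seq_len(n)))
}

# an ordinary graph (all orders 2): 4-cycle
hg_cycle_graph <- function(n = 4) {
  hypergraph(lapply(seq_len(n), function(i) c(i, i %% n + 1)))
}

# random connected hypergraph for property tests (small N)
random_hypergraph <- function(N = 7, E = 5, seed = 1) {
  set.seed(seed)
  repeat {
    edges <- lapply(seq_len(E), function(e) {
      g <- sample(2:min(4, N), 1)
      sample.int(N, g)
    })
    H <- try(hypergraph(edges, labels = as.character(seq_len(N))),
             silent = TRUE)
    if (!inherits(H, "try-error")) return(H)
  }
}

expect_handshake <- function(H) {
  expect_identical(sum(hyperdegrees(H)), sum(hyperedge_orders(H)))
}
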