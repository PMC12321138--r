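#' Higher-order random-walk matrices
#'
#' A walker at node `i` first picks one of its `k_i` adjacent hyperedges
#' uniformly, then a member of that hyperedge uniformly. Excluding the
#' current node from the member choice gives the no-self-loop walk
#' \deqn{\tilde p_{ij} = \sum_e \frac{b(i,e)\,b(j,e)}{k_i\,(g_e - 1)}, \quad j \neq i,}
#' including it gives the lazy walk
#' \deqn{\hat p_{ij} = \sum_e \frac{b(i,e)\,b(j,e)}{k_i\,g_e}.}
#' Both matrices are row-stochastic and reversible with respect to the
#' hyperdegree distribution `pi_i = k_i / sum(k)` (the numerator
#' `sum_e b(i,e) b(j,e) / (g_e - 1)` resp. `/ g_e` is symmetric in `i, j`).
#'
#' @param H a [hypergraph()]
#' @return a dense `N x N` row-stochastic matrix
#' @examples
#' walk_matrix_noself(hg_example9())["6", ] # all mass on node 7
#' @export
walk_matrix_noself <- function(H) {
  stopifnot(inherits(H, "hypergraph"))
  B <- incidence_matrix(H)
  g <- hyperedge_orders(H)
  k <- hyperdegrees(H)
  P <- as.matrix(B %*% Matrix::Diagonal(H$E, 1 / (g - 1)) %*% Matrix::t(B)) / k
  diag(P) <- 0
  dimnames(P) <- list(H$labels, H$labels)
  P
}

#' @rdname walk_matrix_noself
#' @export
walk_matrix_self <- function(H) {
  stopifnot(inherits(H, "hypergraph"))
  B <- incidence_matrix(H)
  g <- hyperedge_orders(H)
  k <- hyperdegrees(H)
  P <- as.matrix(B %*% Matrix::Diagonal(H$E, 1 / g) %*% Matrix::t(B)) / k
  dimnames(P) <- list(H$labels, H$labels)
  P
}

#' (n, m)-hop composite walk
#'
#' The probability of reaching `j` from `i` by `n` hops of the no-self-loop
#' walk followed by `m` hops of the lazy walk:
#' \eqn{p^{(n,m)} = \tilde p^{\,n} \hat p^{\,m}}, with
#' \eqn{p^{(0,0)} = I}.
#'
#' @param H a [hypergraph()]
#' @param n hops without self-loops, `>= 0`
#' @param m hops with self-loops, `>= 0`
#' @return a dense `N x N` row-stochastic matrix
#' @export
walk_nm_hop <- function(H, n, m) {
  stopifnot(inherits(H, "hypergraph"))
  if (n < 0 || m < 0) stop("hop counts must be non-negative", call. = FALSE)
  P <- diag(H$N)
  dimnames(P) <- list(H$labels, H$labels)
  if (n > 0) {
    Pt <- walk_matrix_noself(H)
    for (s in seq_len(n)) P <- P %*% Pt
  }
  if (m > 0) {
    Ph <- walk_matrix_self(H)
    for (s in seq_len(m)) P <- P %*% Ph
  }
  P
}

#' Stationary distribution of the higher-order walks
#'
#' Both walk matrices share the stationary (and reversible) distribution
#' `pi_i = k_i / sum_j k_j`, the normalized hyperdegree.
#'
#' @param H a [hypergraph()]
#' @return a probability vector of length `N`, named by node label
#' @export
stationary_distribution <- function(H) {
  k <- hyperdegrees(H)
  k / sum(k)
}
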