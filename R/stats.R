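#' Structural and correlation statistics of a hypergraph
#'
#' Computes the scalar summaries that the closed-form critical synergy
#' factors depend on:
#'
#' * `mean_hyperdegree` \eqn{\langle k\rangle} and `mean_order`
#'   \eqn{\langle g\rangle}, with second moments `k2`, `g2`;
#' * heterogeneities \eqn{\eta_k = \langle k^2\rangle/\langle k\rangle^2}
#'   and \eqn{\eta_g = \langle g^2\rangle/\langle g\rangle^2}, both `>= 1`
#'   with equality iff the sequence is constant;
#' * the hyperdegree-order assortativity
#'   \eqn{\zeta = \frac{1}{N\langle k\rangle^2}\sum_{\alpha}\sum_{i\in\alpha} g_\alpha k_i},
#'   which equals `g` on every homogeneous hypergraph;
#' * two overlap strengths, summed over ordered pairs of distinct hyperedges
#'   (each unordered pair contributes twice):
#'   \eqn{\hat\theta = \frac{1}{N\langle k\rangle}\sum_{\alpha\neq\beta}\sum_{i\in\alpha\cap\beta}\frac{|\alpha\cap\beta|}{k_i g_\alpha}}
#'   and
#'   \eqn{\tilde\theta = \frac{1}{N\langle k\rangle}\sum_{\alpha\neq\beta}\sum_{i\in\alpha\cap\beta}\frac{|\alpha\cap\beta|-1}{k_i (g_\alpha-1)}};
#' * for homogeneous hypergraphs only, the rescaled overlap strength
#'   `c_ovl` (see [rescaled_overlap()]); `NA` otherwise.
#'
#' On homogeneous hypergraphs \eqn{\hat\theta = (1 - 1/k)\,C_{\mathrm{ovl}}},
#' and \eqn{\tilde\theta = 0} whenever no two hyperedges share more than one
#' node.
#'
#' @param H a [hypergraph()]
#' @return A one-row tibble with columns `n_nodes`, `n_edges`,
#'   `mean_hyperdegree`, `mean_order`, `k2`, `g2`, `eta_k`, `eta_g`, `zeta`,
#'   `theta_hat`, `theta_tilde`, `c_ovl`.
#' @examples
#' hypergraph_stats(hg_window_ring(12, 3))
#' @export
hypergraph_stats <- function(H) {
  stopifnot(inherits(H, "hypergraph"))
  k <- as.numeric(hyperdegrees(H))
  g <- as.numeric(hyperedge_orders(H))
  N <- H$N
  mean_k <- mean(k)
  mean_g <- mean(g)
  k2 <- mean(k^2)
  g2 <- mean(g^2)

  # zeta: per membership (i in alpha), add g_alpha * k_i
  members <- unlist(H$edges, use.names = FALSE)
  g_per_member <- rep(g, lengths(H$edges))
  zeta <- sum(g_per_member * k[members]) / (N * mean_k^2)

  ov <- overlap_sums(H, k, g)

  tibble::tibble(
    n_nodes = N, n_edges = H$E,
    mean_hyperdegree = mean_k, mean_order = mean_g,
    k2 = k2, g2 = g2,
    eta_k = k2 / mean_k^2, eta_g = g2 / mean_g^2,
    zeta = zeta,
    theta_hat = ov$theta_hat / (N * mean_k),
    theta_tilde = ov$theta_tilde / (N * mean_k),
    c_ovl = if (is_homogeneous(H) && k[1] >= 2) rescaled_overlap(H) else NA_real_
  )
}

# Unnormalized overlap sums over ordered pairs of distinct hyperedges.
# For each unordered pair {alpha, beta} with intersection size q > 0 the
# ordered sum receives the (alpha, beta) and (beta, alpha) terms; the inner
# sums run over the q shared nodes.
overlap_sums <- function(H, k = NULL, g = NULL) {
  if (is.null(k)) k <- as.numeric(hyperdegrees(H))
  if (is.null(g)) g <- as.numeric(hyperedge_orders(H))
  th_hat <- 0
  th_tilde <- 0
  sq <- 0
  E <- H$E
  # group hyperedges by node to enumerate only adjacent pairs
  by_node <- vector("list", H$N)
  for (a in seq_len(E)) for (i in H$edges[[a]]) {
    by_node[[i]] <- c(by_node[[i]], a)
  }
  pair_seen <- new.env(hash = TRUE, size = 4L * E)
  for (i in seq_len(H$N)) {
    es <- by_node[[i]]
    if (length(es) < 2) next
    for (ai in seq_len(length(es) - 1L)) for (bi in seq.int(ai + 1L, length(es))) {
      a <- es[ai]; b <- es[bi]
      key <- paste0(a, "_", b)
      if (!is.null(pair_seen[[key]])) next
      pair_seen[[key]] <- TRUE
      shared <- intersect(H$edges[[a]], H$edges[[b]])
      q <- length(shared)
      inv_k <- sum(1 / k[shared])
      # ordered pair (a,b): focal order g_a; (b,a): focal order g_b
      th_hat <- th_hat + q * inv_k * (1 / g[a] + 1 / g[b])
      th_tilde <- th_tilde + (q - 1) * inv_k * (1 / (g[a] - 1) + 1 / (g[b] - 1))
      sq <- sq + 2 * q^2
    }
  }
  list(theta_hat = th_hat, theta_tilde = th_tilde, sumsq = sq)
}

#' Rescaled overlap strength of a homogeneous hypergraph
#'
#' For a homogeneous hypergraph (constant hyperdegree `k >= 2`, constant
#' order `g`) the overlap strength is
#' \deqn{C_{\mathrm{ovl}} = \frac{\sum_{\alpha\neq\beta} |\alpha\cap\beta|^2}{N k (k-1) g},}
#' the sum running over ordered pairs of distinct hyperedges. It ranges from
#' `1/g` (every pair of adjacent hyperedges shares exactly one node) to 1
#' (overlaps as large as the order itself). Larger values mean that the same
#' individuals meet each other in several groups.
#'
#' @param H a homogeneous [hypergraph()] with constant hyperdegree `k >= 2`
#' @return the overlap strength, a number in `[1/g, 1]`
#' @examples
#' rescaled_overlap(hg_window_ring(30, 3)) # 5/9
#' @export
rescaled_overlap <- function(H) {
  stopifnot(inherits(H, "hypergraph"))
  if (!is_homogeneous(H)) {
    stop("the rescaled overlap strength is defined for homogeneous ",
         "hypergraphs only (constant hyperdegree and order)", call. = FALSE)
  }
  k <- hyperdegrees(H)[[1]]
  g <- hyperedge_orders(H)[[1]]
  if (k < 2) {
    stop("rescaled overlap requires constant hyperdegree k >= 2", call. = FALSE)
  }
  ov <- overlap_sums(H)
  ov$sumsq / (H$N * k * (k - 1) * g)
}
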