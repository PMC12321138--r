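#' Mechanisms implemented by the package
#'
#' Five higher-order strategy-update mechanisms, each a two-stage selection
#' (pick an adjacent hyperedge, then an individual within it):
#'
#' * `"HDB"` higher-order death-birth: hyperedge chosen proportional to the
#'   group fitness of its members excluding the focal (dead) individual;
#'   member chosen within the hyperedge proportional to individual fitness;
#'   the focal adopts that member's strategy.
#' * `"HIM"` higher-order imitation: as HDB but the focal individual is
#'   included in both the group-fitness calculation and the member
#'   selection (self-selection keeps the current strategy).
#' * `"GMC"` group-mutual comparison: hyperedge chosen proportional to full
#'   group fitness, member chosen uniformly among the other members.
#' * `"GIC"` group-inner comparison: hyperedge chosen uniformly, member
#'   chosen proportional to fitness among the other members.
#' * `"HPC"` higher-order pair comparison: hyperedge and member both
#'   uniform; the focal adopts the peer's strategy with the Fermi
#'   probability `f_j / (f_i + f_j)`.
#'
#' @format A character vector of the five mechanism codes.
#' @export
mechanisms <- c("HDB", "HIM", "GMC", "GIC", "HPC")

match_mechanism <- function(mechanism) {
  m <- toupper(mechanism)
  if (length(m) != 1 || !m %in% mechanisms) {
    stop("`mechanism` must be one of ", paste(mechanisms, collapse = ", "),
         call. = FALSE)
  }
  m
}

#' Payoffs in a single isolated public goods game
#'
#' In a group of size `g` with `gc` cooperators, each cooperator invests a
#' cost `c`; the pot `gc * c` is multiplied by the local synergy factor `R`
#' and shared equally, so
#' `u_C = gc * R * c / g - c` and `u_D = gc * R * c / g`.
#' Defection dominates pointwise (`u_D - u_C = c`), which is the dilemma.
#'
#' @param g group size
#' @param gc number of cooperators in the group, `0 <= gc <= g`
#' @param R local synergy factor
#' @param cost cooperation cost (default 1)
#' @return a named numeric vector `c(u_C = ..., u_D = ...)`
#' @export
pgg_payoffs_isolated <- function(g, gc, R, cost = 1) {
  if (gc < 0 || gc > g) stop("need 0 <= gc <= g", call. = FALSE)
  share <- gc * R * cost / g
  c(u_C = share - cost, u_D = share)
}

#' Per-node payoffs of a strategy state on a hypergraph
#'
#' Every hyperedge `e` hosts a public goods game with local synergy factor
#' `R_e = r * g_e` (so the global synergy factor `r` is shared across
#' hyperedges of different order). Node `i` averages its payoff over its
#' `k_i` games:
#' \deqn{u_i(s) = \frac{r}{k_i} \sum_{e \ni i} \sum_{j \in e} s_j \; - \; s_i c.}
#'
#' @param H a [hypergraph()]
#' @param s binary state vector of length `N` (1 = cooperator, 0 = defector)
#' @param r global synergy factor
#' @param cost cooperation cost (default 1)
#' @return a numeric payoff vector of length `N`
#' @examples
#' H <- hg_example9()
#' pgg_payoffs(H, rep(1, 9), r = 1)  # u_5 = 4r - 1, u_6 = 2r - 1
#' @export
pgg_payoffs <- function(H, s, r, cost = 1) {
  stopifnot(inherits(H, "hypergraph"))
  s <- check_state(H, s)
  k <- hyperdegrees(H)
  coop <- vapply(H$edges, function(e) sum(s[e]), 0)
  tot <- numeric(H$N)
  for (a in seq_len(H$E)) {
    e <- H$edges[[a]]
    tot[e] <- tot[e] + coop[a]
  }
  unname(r * tot / k - s * cost)
}

check_state <- function(H, s) {
  s <- as.numeric(s)
  if (length(s) != H$N || !all(s %in% c(0, 1))) {
    stop("`s` must be a binary vector of length N = ", H$N, call. = FALSE)
  }
  s
}

#' Exponential fitness and group fitness
#'
#' Individual fitness is `f_i = exp(delta * u_i)`, with selection strength
#' `delta` in `[0, 1)`; `delta = 0` is neutral drift (all fitnesses 1).
#' The fitness of a hyperedge is the mean fitness of its members,
#' `F_e = sum_{i in e} f_i / g_e`.
#'
#' @param u payoff vector
#' @param delta selection strength, `0 <= delta < 1`
#' @return `fitness()`: a vector like `u`; `group_fitness()`: a vector of
#'   length `E`.
#' @export
fitness <- function(u, delta) {
  if (delta < 0 || delta >= 1) stop("need 0 <= delta < 1", call. = FALSE)
  exp(delta * u)
}

#' @rdname fitness
#' @param H a [hypergraph()]
#' @param f per-node fitness vector
#' @export
group_fitness <- function(H, f) {
  stopifnot(inherits(H, "hypergraph"), length(f) == H$N)
  vapply(H$edges, function(e) mean(f[e]), 0)
}

#' Exact one-step update kernel of a mechanism
#'
#' Returns the `N x N` matrix `K` in which, for `j != i`, `K[i, j]` is the
#' probability that a focal node `i` adopts node `j`'s strategy in one
#' update under the given mechanism, state and parameters; `K[i, i]` is the
#' residual probability that `i` keeps its strategy (self-selection under
#' HIM, rejected comparisons under HPC). Rows sum to 1.
#'
#' At `delta = 0` the kernels reduce to the walk matrices: HDB, GMC and GIC
#' give the no-self-loop walk, HIM gives the lazy walk, and HPC gives half
#' the no-self-loop walk off-diagonal (each comparison is accepted with
#' probability 1/2 under equal fitness).
#'
#' @param H a [hypergraph()]
#' @param s binary state vector
#' @param mechanism one of [mechanisms]
#' @param r global synergy factor
#' @param delta selection strength
#' @return a dense row-stochastic `N x N` matrix
#' @export
update_kernel <- function(H, s, mechanism, r, delta) {
  mechanism <- match_mechanism(mechanism)
  s <- check_state(H, s)
  u <- pgg_payoffs(H, s, r)
  f <- fitness(u, delta)
  N <- H$N
  k <- hyperdegrees(H)
  g <- hyperedge_orders(H)
  fsum <- vapply(H$edges, function(e) sum(f[e]), 0)
  K <- matrix(0, N, N, dimnames = list(H$labels, H$labels))

  if (mechanism == "HPC") {
    Pt <- walk_matrix_noself(H)
    A <- Pt * outer(f, f, function(fi, fj) fj / (fi + fj))
    diag(A) <- 0
    diag(A) <- 1 - rowSums(A)
    return(A)
  }

  for (i in seq_len(N)) {
    es <- which(vapply(H$edges, function(e) i %in% e, TRUE))
    w <- switch(mechanism,
      GMC = fsum[es] / g[es],
      HDB = (fsum[es] - f[i]) / (g[es] - 1),
      HIM = fsum[es] / g[es],
      GIC = rep(1, length(es))
    )
    w <- w / sum(w)
    for (a in seq_along(es)) {
      e <- H$edges[[es[a]]]
      if (mechanism == "GMC") {
        others <- setdiff(e, i)
        K[i, others] <- K[i, others] + w[a] / (g[es[a]] - 1)
      } else if (mechanism == "HIM") {
        K[i, e] <- K[i, e] + w[a] * f[e] / fsum[es[a]]
      } else { # HDB, GIC: fitness-proportional among others
        others <- setdiff(e, i)
        K[i, others] <- K[i, others] + w[a] * f[others] / (fsum[es[a]] - f[i])
      }
    }
  }
  K
}

#' One-step strategy-flip probabilities
#'
#' For each focal node `i`, the probability that a single update applied to
#' `i` changes its strategy, i.e. the kernel mass on nodes currently playing
#' the opposite strategy. Used by the exact fixation solver.
#'
#' @inheritParams update_kernel
#' @return a numeric vector of length `N`
#' @export
flip_probabilities <- function(H, s, mechanism, r, delta) {
  s <- check_state(H, s)
  K <- update_kernel(H, s, mechanism, r, delta)
  opp <- outer(s, s, `!=`)
  unname(rowSums(K * opp))
}
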