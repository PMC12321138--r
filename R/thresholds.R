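#' Closed-form critical synergy factors
#'
#' The critical synergy factor `r*` is the smallest global synergy factor at
#' which a single cooperator is favoured by selection (`rho_C > 1/N`) under
#' weak selection. It has a closed form in the hypergraph's structural
#' summaries for each mechanism:
#'
#' \deqn{r^*_{\mathrm{HDB}} = \frac{N - 2\eta_k}{N + N/\langle k\rangle + N\tilde\theta - 2\zeta}}
#' \deqn{r^*_{\mathrm{HIM}} = \frac{N + N/\langle g\rangle - 2\eta_k}{N + N/\langle k\rangle + N\hat\theta - 2\zeta}}
#' \deqn{r^*_{\mathrm{GMC}} = \frac{N/\langle g\rangle - \eta_k}{N/\langle k\rangle + N\hat\theta - \zeta}}
#' \deqn{r^*_{\mathrm{GIC}} = r^*_{\mathrm{HPC}} = \frac{N - \eta_k}{N - \zeta}}
#'
#' (see [hypergraph_stats()] for the summaries). A value below 1 means the
#' structure promotes cooperation relative to an isolated public goods
#' game; values may fall outside `(0, 1)` for extreme structures and are
#' returned as-is.
#'
#' @param H a [hypergraph()], or a one-row stats tibble from
#'   [hypergraph_stats()]
#' @param mechanism one of [mechanisms], or `"all"`
#' @return A tibble with one row per mechanism: `mechanism`, `r_star`,
#'   `promotes_cooperation` (`r_star` in `(0, 1)`), plus the structural
#'   summaries used.
#' @examples
#' critical_r(hg_window_ring(30, 3), "all")
#' @export
critical_r <- function(H, mechanism = "all") {
  st <- if (inherits(H, "hypergraph")) hypergraph_stats(H) else H
  stopifnot(is.data.frame(st), nrow(st) == 1)
  mechs <- if (identical(mechanism, "all")) mechanisms else
    vapply(mechanism, match_mechanism, "")
  N <- st$n_nodes
  r <- vapply(mechs, function(m) {
    num <- switch(m,
      HDB = N - 2 * st$eta_k,
      HIM = N + N / st$mean_order - 2 * st$eta_k,
      GMC = N / st$mean_order - st$eta_k,
      GIC = ,
      HPC = N - st$eta_k
    )
    den <- switch(m,
      HDB = N + N / st$mean_hyperdegree + N * st$theta_tilde - 2 * st$zeta,
      HIM = N + N / st$mean_hyperdegree + N * st$theta_hat - 2 * st$zeta,
      GMC = N / st$mean_hyperdegree + N * st$theta_hat - st$zeta,
      GIC = ,
      HPC = N - st$zeta
    )
    if (abs(den) < .Machine$double.eps * N) {
      stop("degenerate structure: zero denominator in the ", m,
           " threshold", call. = FALSE)
    }
    num / den
  }, 0)
  tibble::tibble(
    mechanism = unname(mechs), r_star = unname(r),
    promotes_cooperation = unname(r) > 0 & unname(r) < 1,
    n_nodes = N, mean_hyperdegree = st$mean_hyperdegree,
    mean_order = st$mean_order, eta_k = st$eta_k, zeta = st$zeta,
    theta_hat = st$theta_hat, theta_tilde = st$theta_tilde
  )
}

#' GMC threshold for homogeneous hypergraphs from the overlap strength
#'
#' On a homogeneous hypergraph (constant hyperdegree `k`, order `g`) the
#' group-mutual-comparison threshold depends on structure only through the
#' rescaled overlap strength:
#' \deqn{r^* = \frac{N/g - 1}{N/k + N(1 - 1/k)\,C_{\mathrm{ovl}} - g}.}
#' It is strictly decreasing in `c_ovl`: stronger overlap lowers the bar
#' for cooperation.
#'
#' @param N population size
#' @param k constant hyperdegree
#' @param g constant order
#' @param c_ovl rescaled overlap strength in `[1/g, 1]`
#' @return the critical synergy factor
#' @examples
#' rstar_gmc_homogeneous(1000, 2, 4, 1 / 4) # 249/621
#' @export
rstar_gmc_homogeneous <- function(N, k, g, c_ovl) {
  den <- N / k + N * (1 - 1 / k) * c_ovl - g
  if (den <= 0) stop("nonpositive denominator: structure too small or ",
                     "overlap infeasible", call. = FALSE)
  (N / g - 1) / den
}

#' GMC threshold from the lazy higher-order random walk
#'
#' The general (structure-only) form of the group-mutual-comparison
#' threshold on an arbitrary hypergraph:
#' \deqn{r^* = \frac{\sum_v \pi_v (\hat p_{vv} - \pi_v)}
#'                 {\sum_{i,v} \pi_v (\hat p_{vi} - \pi_i)\, m_{iv} / k_i},}
#' where \eqn{\hat p} is the lazy one-step walk ([walk_matrix_self()]),
#' \eqn{\pi} the stationary hyperdegree distribution and
#' \eqn{m_{iv} = \sum_e b(i,e) b(v,e)} the shared-hyperedge counts. On
#' homogeneous hypergraphs it coincides with the closed form in
#' [critical_r()] and with [rstar_gmc_homogeneous()].
#'
#' @param H a [hypergraph()]
#' @return the critical synergy factor
#' @export
rstar_gmc_walk <- function(H) {
  stopifnot(inherits(H, "hypergraph"))
  p_hat <- walk_matrix_self(H)
  pi_v <- unname(stationary_distribution(H))
  k <- unname(hyperdegrees(H))
  m <- shared_edge_counts(H)
  num <- sum(pi_v * (diag(p_hat) - pi_v))
  # denominator: sum_{i,v} pi_v (p_hat[v,i] - pi_i) m[i,v] / k_i
  dev <- sweep(p_hat, 2, pi_v, `-`)          # [v, i]
  den <- sum((pi_v * dev) * t(m / k))
  if (abs(den) < .Machine$double.eps) {
    stop("zero denominator in the walk-based threshold", call. = FALSE)
  }
  num / den
}

#' Pairwise (graph) thresholds as order-2 degenerations
#'
#' When every hyperedge has order 2 the hypergraph is an ordinary graph and
#' the higher-order mechanisms reduce to their pairwise counterparts:
#' higher-order death-birth to death-birth (DB), higher-order pair
#' comparison to pair comparison (PC). This helper evaluates the same
#' closed forms and labels them with the pairwise rule names; on such
#' graphs GMC and HDB coincide.
#'
#' @param H a [hypergraph()] whose hyperedges all have order 2
#' @return a tibble like [critical_r()] with an extra `pairwise_rule`
#'   column (`DB`, `IM`, `PC`, ... )
#' @export
rstar_pairwise <- function(H) {
  stopifnot(inherits(H, "hypergraph"))
  if (any(hyperedge_orders(H) != 2)) {
    stop("pairwise degeneration requires every hyperedge to have order 2",
         call. = FALSE)
  }
  out <- critical_r(H, "all")
  map <- c(HDB = "DB", HIM = "IM", GMC = "DB", GIC = "IC", HPC = "PC")
  dplyr::mutate(out, pairwise_rule = unname(map[.data$mechanism]),
                .after = "mechanism")
}

#' Threshold sweep over a family of generated hypergraphs
#'
#' Evaluates the closed-form thresholds across a grid of structural
#' parameters, generating one hypergraph per grid point. Supported sweeps:
#'
#' * `vary = "k"`: weak-overlap homogeneous hypergraphs, constant order
#'   `g`, hyperdegree along `grid`;
#' * `vary = "g"`: constant hyperdegree `k`, order along `grid`;
#' * `vary = "eta_k"`: configuration-model hypergraphs with power-law
#'   hyperdegree sequences of fixed mean and constant orders, one exponent
#'   per grid entry;
#' * `vary = "eta_g"`: constant hyperdegrees, Poisson-spread orders whose
#'   dispersion is controlled by mixing two order values.
#'
#' @param vary one of `"k"`, `"g"`, `"eta_k"`, `"eta_g"`
#' @param grid numeric vector of parameter values (for `eta_k`/`eta_g`,
#'   power-law exponents / mixing weights)
#' @param N population size
#' @param k,g the fixed counterpart parameter
#' @param mechanisms_used subset of [mechanisms]
#' @param mean_k,mean_g target means for the heterogeneity sweeps
#' @param seed RNG seed for the generated instances
#' @return a tibble: one row per (grid point, mechanism) with the realized
#'   structural summaries and `r_star`; classed `threshold_sweep` for
#'   [ggplot2::autoplot()]
#' @export
threshold_sweep <- function(vary = c("k", "g", "eta_k", "eta_g"), grid,
                            N = 100, k = 4, g = 4,
                            mechanisms_used = c("GMC", "HDB", "HIM"),
                            mean_k = 8, mean_g = 8, seed = 1) {
  vary <- match.arg(vary)
  set.seed(seed)
  rows <- purrr::map_dfr(seq_along(grid), function(ii) {
    val <- grid[ii]
    H <- switch(vary,
      k = {
        if ((N * val) %% g != 0) {
          stop("N * k must be divisible by g for a homogeneous hypergraph ",
               "(N = ", N, ", k = ", val, ", g = ", g, ")", call. = FALSE)
        }
        hg_homogeneous_weak(val, g, n_edges = N * val / g)
      },
      g = {
        if ((N * k) %% val != 0) {
          stop("N * k must be divisible by g for a homogeneous hypergraph ",
               "(N = ", N, ", k = ", k, ", g = ", val, ")", call. = FALSE)
        }
        hg_homogeneous_weak(k, val, n_edges = N * k / val)
      },
      eta_k = {
        k_seq <- sample_sequence("powerlaw", N, exponent = val,
                                 min_value = 2, max_value = N / 2)
        k_seq <- match_sequence_total(
          k_seq, round(sum(k_seq) / mean_g) * mean_g, min_value = 2)
        g_seq <- rep(mean_g, sum(k_seq) / mean_g)
        hg_configuration_model(k_seq, g_seq)
      },
      eta_g = {
        # mix orders mean_g +/- spread; val in [0, mean_g - 2] controls eta_g
        g_lo <- round(mean_g - val); g_hi <- round(mean_g + val)
        n_e <- round(N * mean_k / mean_g)
        g_seq <- rep(c(g_lo, g_hi), length.out = n_e)
        g_seq <- match_sequence_total(g_seq, N * mean_k, min_value = 2)
        hg_configuration_model(rep(mean_k, N), g_seq)
      }
    )
    out <- critical_r(H, "all")
    out <- dplyr::filter(out, .data$mechanism %in% mechanisms_used)
    st <- hypergraph_stats(H)
    dplyr::mutate(out, sweep = vary, value = val, eta_g = st$eta_g,
                  .before = 1)
  })
  class(rows) <- c("threshold_sweep", class(rows))
  rows
}
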