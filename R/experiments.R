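#' Fixation-probability curves across a synergy-factor grid
#'
#' For each mechanism and each synergy factor on the grid, estimates the
#' relative fixation probability `rho_C * N` by Monte Carlo and appends the
#' closed-form critical synergy factor of the mechanism on the same
#' hypergraph. The crossing of `rho_C * N` through the neutral baseline 1
#' should occur near the closed-form value under weak selection.
#'
#' @param H a [hypergraph()]
#' @param mechanisms_used subset of [mechanisms]
#' @param r_grid strictly increasing synergy factors
#' @param delta selection strength
#' @param replicates Monte Carlo replicates per point
#' @param seed RNG seed (one stream; points are simulated in order)
#' @return a tibble with one row per (mechanism, r): `rho`, `rho_N`,
#'   Wilson interval, `replicates`, and `r_star_analytic`; classed
#'   `fixation_curves` for [ggplot2::autoplot()]
#' @export
fixation_curves <- function(H, mechanisms_used = mechanisms, r_grid,
                            delta = 0.025, replicates = 1e4, seed = 1) {
  stopifnot(inherits(H, "hypergraph"), all(diff(r_grid) > 0))
  set.seed(seed)
  rstar <- critical_r(H, "all")
  rows <- purrr::map_dfr(mechanisms_used, function(m) {
    purrr::map_dfr(r_grid, function(r) {
      fr <- simulate_fixation(H, m, r, delta, replicates)
      tibble::tibble(mechanism = m, r = r, rho = fr$rho,
                     rho_N = fr$rho * H$N,
                     ci_low = fr$ci_low * H$N, ci_high = fr$ci_high * H$N,
                     replicates = replicates)
    })
  })
  rows <- dplyr::left_join(
    rows,
    dplyr::select(rstar, "mechanism", r_star_analytic = "r_star"),
    by = "mechanism"
  )
  attr(rows, "delta") <- delta
  attr(rows, "n_nodes") <- H$N
  class(rows) <- c("fixation_curves", class(rows))
  rows
}

#' Overlap-family comparison of critical synergy factors
#'
#' Builds the homogeneous overlap families at fixed `(k, g)` and compares
#' the GMC, HDB, HIM thresholds as the rescaled overlap strength increases:
#'
#' * `(k = 2, g = 4)`: weak (`c_ovl = 1/4`, minimal-overlap family),
#'   moderate (`1/2`, ring of hyperedges sharing two nodes), strong
#'   (`5/8`, dimer chain);
#' * `(k = 3, g = 3)`: weak (`1/3`) and strong (`5/9`, sliding-window
#'   ring).
#'
#' Stronger overlap lowers the threshold for all three mechanisms.
#'
#' @param family `"k2g4"` or `"k3g3"`
#' @param N population size (multiples of 4 for `k2g4`)
#' @param mechanisms_used subset of [mechanisms]
#' @param seed RNG seed for the randomized weak-overlap construction
#' @return a tibble: one row per (overlap family, mechanism) with `c_ovl`
#'   and `r_star`; classed `overlap_comparison` for [ggplot2::autoplot()]
#' @export
overlap_comparison <- function(family = c("k2g4", "k3g3"), N = 1000,
                               mechanisms_used = c("GMC", "HDB", "HIM"),
                               seed = 1) {
  family <- match.arg(family)
  hs <- if (family == "k2g4") {
    stopifnot(N %% 4 == 0)
    list(
      weak = hg_homogeneous_weak(2, 4, n_edges = N / 2, seed = seed),
      moderate = hg_ring_overlap(g = 4, overlap = 2, n_edges = N / 2),
      strong = hg_dimer_chain(n_dimers = N / 4)
    )
  } else {
    list(
      weak = hg_homogeneous_weak(3, 3, n_edges = N, seed = seed),
      strong = hg_window_ring(N, 3)
    )
  }
  rows <- purrr::imap_dfr(hs, function(H, nm) {
    out <- critical_r(H, "all")
    out <- dplyr::filter(out, .data$mechanism %in% mechanisms_used)
    dplyr::mutate(out, family = family, overlap = nm,
                  c_ovl = rescaled_overlap(H), .before = 1)
  })
  class(rows) <- c("overlap_comparison", class(rows))
  rows
}

#' Structural sweeps of the closed-form thresholds
#'
#' Convenience presets around [threshold_sweep()]: hyperdegree at fixed
#' order 4, order at fixed hyperdegree 4 (homogeneous hypergraphs of size
#' `N`), and the heterogeneity sweeps at mean hyperdegree and order 8.
#' The default `N = 120` keeps `N * k / g` integral across the whole order
#' grid (a `(k, g)`-biregular hypergraph requires `g` to divide `N * k`).
#'
#' @param N population size
#' @param seed RNG seed
#' @return a named list of `threshold_sweep` tibbles (`k`, `g`, `eta_k`,
#'   `eta_g`)
#' @export
structure_sweeps <- function(N = 120, seed = 1) {
  list(
    k = threshold_sweep("k", grid = c(2, 4, 5), N = N, g = 4, seed = seed),
    g = threshold_sweep("g", grid = 2:6, N = N, k = 4, seed = seed),
    eta_k = threshold_sweep("eta_k", grid = c(6, 3.5, 2.5), N = N,
                            mean_k = 8, mean_g = 8, seed = seed),
    eta_g = threshold_sweep("eta_g", grid = c(0, 2, 4, 6), N = N,
                            mean_k = 8, mean_g = 8, seed = seed)
  )
}

#' @export
autoplot.fixation_curves <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$r, y = .data$rho_N,
                                       colour = .data$mechanism)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$r_star_analytic,
                                     colour = .data$mechanism),
                        linetype = "dotted", show.legend = FALSE) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high),
                             size = 0.3) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "synergy factor r",
                  y = expression(rho[C] %*% N),
                  colour = "mechanism",
                  title = "Relative fixation probability vs synergy factor",
                  subtitle = "dotted verticals: closed-form critical synergy factors") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.overlap_comparison <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$c_ovl, y = .data$r_star,
                                       colour = .data$mechanism)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(C[ovl]), y = expression(r^"*"),
                  title = "Stronger hyperedge overlap lowers the cooperation threshold") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.threshold_sweep <- function(object, ...) {
  xlab <- unique(object$sweep)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$value, y = .data$r_star,
                                       colour = .data$mechanism)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = xlab, y = expression(r^"*"),
                  title = paste("Critical synergy factor vs", xlab)) +
    ggplot2::theme_minimal()
}
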