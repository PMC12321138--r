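# CSR encoding of a hypergraph for the C++ simulation core (0-based).
hg_csr <- function(H) {
  g <- lengths(H$edges)
  edge_ptr <- c(0L, cumsum(g))
  edge_nodes <- unlist(H$edges, use.names = FALSE) - 1L
  by_node <- vector("list", H$N)
  for (a in seq_len(H$E)) for (i in H$edges[[a]]) {
    by_node[[i]] <- c(by_node[[i]], a - 1L)
  }
  node_ptr <- c(0L, cumsum(lengths(by_node)))
  list(edge_ptr = as.integer(edge_ptr),
       edge_nodes = as.integer(edge_nodes),
       node_ptr = as.integer(node_ptr),
       node_edges = as.integer(unlist(by_node, use.names = FALSE)))
}

mech_code <- function(mechanism) {
  match(match_mechanism(mechanism), c("HDB", "HIM", "GMC", "GIC", "HPC"))
}

#' Run one evolutionary trajectory to absorption
#'
#' Starting from `initial_state`, repeatedly picks a focal node uniformly at
#' random and applies one asynchronous update of the chosen mechanism until
#' the population is all-cooperator or all-defector.
#'
#' @param H a [hypergraph()]
#' @param mechanism one of [mechanisms]
#' @param r global synergy factor
#' @param delta selection strength in `[0, 1)`
#' @param initial_state binary vector of length `N`
#' @param seed optional RNG seed (the trajectory is a deterministic function
#'   of the seed)
#' @param max_steps step cap before a non-absorption error (default `1e8`)
#' @return a list with `fixed_cooperation` (logical), `steps`, and the
#'   absorbing `state`
#' @export
run_to_absorption <- function(H, mechanism, r, delta, initial_state,
                              seed = NULL, max_steps = 1e8) {
  stopifnot(inherits(H, "hypergraph"))
  s <- check_state(H, initial_state)
  if (!is.null(seed)) set.seed(seed)
  csr <- hg_csr(H)
  cpp_run_to_absorption(csr$edge_ptr, csr$edge_nodes, csr$node_ptr,
                        csr$node_edges, as.integer(s),
                        mech_code(mechanism), r, delta, max_steps)
}

wilson_ci <- function(x, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(low = max(0, centre - half), high = min(1, centre + half))
}

#' Monte Carlo estimate of fixation probabilities
#'
#' Each replicate places a single mutant (a cooperator for `rho_C`, a
#' defector for `rho_D`) at a uniformly random node of an otherwise
#' monomorphic population and runs the dynamics to absorption. The fixation
#' probability is the fraction of replicates in which the mutant strategy
#' takes over; a Wilson 95% interval quantifies the Monte Carlo error.
#' Under neutral drift (`delta = 0`) both probabilities equal `1/N`.
#'
#' @inheritParams run_to_absorption
#' @param replicates number of independent trajectories, `>= 1`
#' @param mutant `"cooperator"` (estimates `rho_C`) or `"defector"`
#'   (`rho_D`)
#' @param conf_level confidence level of the Wilson interval
#' @return an object of class `fixation_result`: a list with `rho` (point
#'   estimate), `ci_low`, `ci_high`, `fixed`, `replicates`, `mean_steps`,
#'   `mechanism`, `r`, `delta`, `mutant`, `n_nodes`, `seed`. Use
#'   [generics::tidy()] / [generics::glance()] for tibble views.
#' @examples
#' H <- hg_window_ring(12, 3)
#' simulate_fixation(H, "GMC", r = 0.6, delta = 0, replicates = 200, seed = 1)
#' @export
simulate_fixation <- function(H, mechanism, r, delta, replicates,
                              seed = NULL, mutant = c("cooperator", "defector"),
                              max_steps = 1e8, conf_level = 0.95) {
  stopifnot(inherits(H, "hypergraph"), replicates >= 1)
  mutant <- match.arg(mutant)
  mechanism <- match_mechanism(mechanism)
  if (!is.null(seed)) set.seed(seed)
  csr <- hg_csr(H)
  out <- cpp_fixation_batch(csr$edge_ptr, csr$edge_nodes, csr$node_ptr,
                            csr$node_edges, mech_code(mechanism), r, delta,
                            as.integer(replicates), mutant == "cooperator",
                            max_steps)
  ci <- wilson_ci(out$fixed, replicates, conf_level)
  structure(
    list(rho = out$fixed / replicates,
         ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
         fixed = out$fixed, replicates = replicates,
         mean_steps = out$mean_steps,
         mechanism = mechanism, r = r, delta = delta, mutant = mutant,
         n_nodes = H$N, seed = seed),
    class = "fixation_result"
  )
}

#' @export
print.fixation_result <- function(x, ...) {
  what <- if (x$mutant == "cooperator") "rho_C" else "rho_D"
  cat("Fixation probability (", x$mechanism, ", r = ", x$r,
      ", delta = ", x$delta, ")\n", sep = "")
  cat("  ", what, " = ", signif(x$rho, 4),
      "  [", signif(x$ci_low, 4), ", ", signif(x$ci_high, 4), "]  (",
      x$fixed, "/", x$replicates, " replicates)\n", sep = "")
  cat("  ", what, " * N = ", signif(x$rho * x$n_nodes, 4),
      " (neutral baseline 1)\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Monte Carlo fixation result
#'
#' @param x a `fixation_result` from [simulate_fixation()]
#' @param ... unused
#' @return `tidy()`: one row per estimated quantity with `estimate` and the
#'   Wilson interval; `glance()`: a one-row run summary.
#' @export
tidy.fixation_result <- function(x, ...) {
  tibble::tibble(
    term = if (x$mutant == "cooperator") "rho_C" else "rho_D",
    estimate = x$rho,
    conf.low = x$ci_low, conf.high = x$ci_high,
    relative = x$rho * x$n_nodes
  )
}

#' @rdname tidy.fixation_result
#' @export
glance.fixation_result <- function(x, ...) {
  tibble::tibble(
    mechanism = x$mechanism, r = x$r, delta = x$delta, mutant = x$mutant,
    n_nodes = x$n_nodes, replicates = x$replicates, fixed = x$fixed,
    mean_steps = x$mean_steps
  )
}

#' Exact fixation probabilities by absorbing-chain solve
#'
#' Enumerates all `2^N` strategy states, builds the exact one-step
#' transition probabilities from the mechanism kernel (a focal node is
#' uniform, so a state can only move to itself or to a one-bit neighbour),
#' and solves the absorbing linear system for the probability of reaching
#' all-cooperator. `rho_C` averages the single-cooperator starts; `rho_D`
#' averages the single-defector starts. Intended for small instances
#' (`N <= 12`).
#'
#' @inheritParams run_to_absorption
#' @return a named vector `c(rho_C = ..., rho_D = ...)`
#' @examples
#' exact_fixation(hg_example9(), "GMC", r = 1, delta = 0) # both 1/9
#' @export
exact_fixation <- function(H, mechanism, r, delta) {
  stopifnot(inherits(H, "hypergraph"))
  N <- H$N
  if (N > 12) stop("exact solve limited to N <= 12 (2^N states)", call. = FALSE)
  mechanism <- match_mechanism(mechanism)
  n_states <- 2^N
  bits <- function(ix) as.numeric(bitwAnd(ix, 2^(0:(N - 1))) > 0)
  all_c <- n_states - 1
  # transitions: from state ix, flipping node i moves to ix XOR 2^(i-1)
  trans_i <- integer(0); trans_j <- integer(0); trans_x <- numeric(0)
  stay <- numeric(n_states)
  for (ix in 0:(n_states - 1)) {
    if (ix == 0 || ix == all_c) next
    s <- bits(ix)
    fp <- flip_probabilities(H, s, mechanism, r, delta) / N
    to <- bitwXor(ix, 2^(0:(N - 1)))
    keep <- fp > 0
    trans_i <- c(trans_i, rep(ix + 1L, sum(keep)))
    trans_j <- c(trans_j, to[keep] + 1L)
    trans_x <- c(trans_x, fp[keep])
    stay[ix + 1] <- 1 - sum(fp)
  }
  P <- Matrix::sparseMatrix(i = trans_i, j = trans_j, x = trans_x,
                            dims = c(n_states, n_states))
  Matrix::diag(P) <- stay
  transient <- setdiff(seq_len(n_states), c(1L, all_c + 1L))
  Q <- P[transient, transient, drop = FALSE]
  b <- P[transient, all_c + 1L]
  phi <- Matrix::solve(Matrix::Diagonal(length(transient)) - Q, b)
  phi_all <- numeric(n_states)
  phi_all[transient] <- as.numeric(phi)
  phi_all[all_c + 1L] <- 1
  singles_c <- 2^(0:(N - 1)) + 1L         # one cooperator
  singles_d <- (all_c - 2^(0:(N - 1))) + 1L # one defector
  c(rho_C = mean(phi_all[singles_c]),
    rho_D = mean(1 - phi_all[singles_d]))
}

#' Empirical critical synergy factor from Monte Carlo fixation
#'
#' Locates the synergy factor at which the relative fixation probability
#' `rho_C * N` crosses the neutral baseline 1, inside a user-supplied
#' bracket. Two estimators:
#'
#' * `method = "grid"` (default): evaluates `rho_C * N` at `grid_points`
#'   equally spaced synergy factors and fits a variance-weighted linear
#'   regression; the crossing is where the fit equals 1. Under weak
#'   selection the curve is locally linear in `r`, so pooling the grid
#'   points is far more precise than any single evaluation.
#' * `method = "bisect"`: classical bisection on the Monte Carlo sign of
#'   `rho_C * N - 1`, stopping early when an evaluation's Wilson interval
#'   straddles 1 (statistically indistinguishable from the crossing),
#'   finishing with linear interpolation between the tightest bracket.
#'
#' Both require the bracket to straddle the crossing and error otherwise.
#'
#' @inheritParams simulate_fixation
#' @param lower,upper bracket for the crossing; `rho_C * N - 1` must change
#'   sign between them
#' @param replicates Monte Carlo replicates per evaluation
#' @param method `"grid"` or `"bisect"`
#' @param grid_points number of evaluations for the grid method
#' @param max_iter maximum bisection iterations
#' @return a list with `r_star`, the evaluation `table` (tibble of `r`,
#'   `rho_N`, CI bounds), `method`, and `converged`
#' @export
empirical_rstar <- function(H, mechanism, delta, lower, upper,
                            replicates = 1e5, seed = NULL,
                            method = c("grid", "bisect"),
                            grid_points = 5, max_iter = 8,
                            max_steps = 1e8) {
  stopifnot(inherits(H, "hypergraph"), lower < upper)
  method <- match.arg(method)
  if (delta == 0) {
    stop("at delta = 0 the relative fixation probability is identically 1; ",
         "no crossing exists", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  N <- H$N
  eval_point <- function(r) {
    fr <- simulate_fixation(H, mechanism, r, delta, replicates,
                            max_steps = max_steps)
    tibble::tibble(r = r, rho_N = fr$rho * N,
                   ci_low = fr$ci_low * N, ci_high = fr$ci_high * N,
                   var_rho_N = N^2 * fr$rho * (1 - fr$rho) / replicates)
  }

  if (method == "grid") {
    evals <- purrr::map_dfr(seq(lower, upper, length.out = grid_points),
                            eval_point)
    if (!(min(evals$rho_N) < 1 && max(evals$rho_N) > 1)) {
      stop("bracket [", lower, ", ", upper, "] does not straddle the ",
           "rho_C * N = 1 crossing", call. = FALSE)
    }
    w <- 1 / pmax(evals$var_rho_N, 1e-12)
    fit <- stats::lm(rho_N ~ r, data = evals, weights = w)
    b <- stats::coef(fit)
    if (b[2] <= 0) {
      stop("fitted trend of rho_C * N in r is non-increasing; ",
           "widen the bracket or add replicates", call. = FALSE)
    }
    return(list(r_star = unname((1 - b[1]) / b[2]), table = evals,
                method = method, converged = TRUE))
  }

  lo <- eval_point(lower)
  hi <- eval_point(upper)
  if (!(lo$rho_N < 1 && hi$rho_N > 1)) {
    stop("bracket [", lower, ", ", upper, "] does not straddle the ",
         "rho_C * N = 1 crossing (", signif(lo$rho_N, 3), ", ",
         signif(hi$rho_N, 3), ")", call. = FALSE)
  }
  evals <- dplyr::bind_rows(lo, hi)
  converged <- FALSE
  r_star <- NA_real_
  for (it in seq_len(max_iter)) {
    mid <- eval_point((lo$r + hi$r) / 2)
    evals <- dplyr::bind_rows(evals, mid)
    if (mid$ci_low <= 1 && mid$ci_high >= 1) {
      converged <- TRUE
      r_star <- mid$r
      break
    }
    if (mid$rho_N < 1) lo <- mid else hi <- mid
  }
  if (!converged) {
    # linear interpolation between the tightest bracketing estimates
    r_star <- lo$r + (1 - lo$rho_N) * (hi$r - lo$r) / (hi$rho_N - lo$rho_N)
  }
  list(r_star = r_star, table = dplyr::arrange(evals, .data$r),
       method = method, converged = converged)
}
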