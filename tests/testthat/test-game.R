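test_that("isolated public goods game payoffs follow the sharing rule", {
  expect_equal(pgg_payoffs_isolated(5, 3, 2), c(u_C = 0.2, u_D = 1.2))
  expect_equal(pgg_payoffs_isolated(4, 0, 3), c(u_C = -1, u_D = 0))
  # defection dominates pointwise by exactly the cost
  for (gc in 0:6) {
    u <- pgg_payoffs_isolated(6, gc, 2.5, cost = 1.5)
    expect_equal(u[["u_D"]] - u[["u_C"]], 1.5)
  }
  expect_error(pgg_payoffs_isolated(4, 5, 2), "gc")
})

test_that("hypergraph payoffs average games over adjacent hyperedges", {
  H <- hg_example9()
  expect_equal(pgg_payoffs(H, rep(0, 9), r = 2), rep(0, 9))
  for (r in c(0.5, 1, 2)) {
    u <- pgg_payoffs(H, rep(1, 9), r = r)
    expect_equal(u[5], r * (5 + 4 + 3) / 3 - 1) # node 5: orders 5, 4, 3
    expect_equal(u[6], 2 * r - 1)               # node 6: one order-2 edge
  }
  # a defector in a field of cooperators keeps the share, skips the cost
  s <- rep(1, 9); s[6] <- 0
  u <- pgg_payoffs(H, s, r = 1)
  expect_equal(u[6], (2 - 1) / 1) # one cooperator left in its only edge
})

test_that("fitness is exponential in payoff and group fitness is a mean", {
  u <- c(-1, 0, 2)
  expect_equal(fitness(u, 0), rep(1, 3))
  expect_equal(fitness(u, 0.3), exp(0.3 * u))
  expect_error(fitness(u, 1), "delta")
  H <- hg_single(3)
  f <- c(0.5, 1, 2)
  Fe <- group_fitness(H, f)
  expect_equal(Fe, mean(f))
  expect_gte(Fe, min(f)); expect_lte(Fe, max(f))
})

test_that("neutral-drift kernels reduce to the walk matrices", {
  for (H in list(hg_example9(), hg_small_homog(), random_hypergraph(seed = 9))) {
    set.seed(1)
    s <- rbinom(H$N, 1, 0.5)
    Pt <- walk_matrix_noself(H)
    Ph <- walk_matrix_self(H)
    for (m in c("GMC", "HDB", "GIC")) {
      expect_equal(update_kernel(H, s, m, r = 1, delta = 0), Pt,
                   tolerance = 1e-12)
    }
    expect_equal(update_kernel(H, s, "HIM", r = 1, delta = 0), Ph,
                 tolerance = 1e-12)
    half <- Pt / 2
    diag(half) <- 1 / 2
    expect_equal(update_kernel(H, s, "HPC", r = 1, delta = 0), half,
                 tolerance = 1e-12)
  }
})

test_that("kernels are normalized non-negative distributions for random states", {
  for (seed in 1:4) {
    H <- random_hypergraph(N = 6 + seed, E = 4 + seed, seed = seed)
    set.seed(seed)
    s <- rbinom(H$N, 1, 0.4)
    delta <- runif(1, 0, 0.5)
    r <- runif(1, 0.3, 2)
    for (m in mechanisms) {
      K <- update_kernel(H, s, m, r, delta)
      expect_true(all(K >= -1e-15))
      expect_equal(unname(rowSums(K)), rep(1, H$N), tolerance = 1e-12)
    }
  }
})

test_that("monomorphic states are absorbing under every mechanism", {
  H <- hg_small_homog()
  for (m in mechanisms) {
    for (s in list(rep(0, 6), rep(1, 6))) {
      expect_equal(flip_probabilities(H, s, m, r = 1.5, delta = 0.3),
                   rep(0, 6))
    }
  }
})

test_that("fitness-biased selection favours the fitter neighbour", {
  # single hyperedge: focal 1, neighbours 2 (C) and 3 (D); cooperator-rich
  # payoffs make f_2 < f_3, so HDB picks 3 more often than uniform
  H <- hg_single(3)
  s <- c(0, 1, 0)
  K <- update_kernel(H, s, "HDB", r = 1.2, delta = 0.4)
  expect_gt(K[1, 3], 0.5) # defector has the higher payoff
  expect_lt(K[1, 2], 0.5)
  # GMC within a single hyperedge stays uniform regardless of delta
  Kg <- update_kernel(H, s, "GMC", r = 1.2, delta = 0.4)
  expect_equal(unname(Kg[1, 2:3]), c(0.5, 0.5))
})

test_that("HPC adoption follows the Fermi rule", {
  H <- hg_single(2)
  for (delta in c(0.1, 0.4)) {
    for (r in c(0.5, 1.5)) {
      s <- c(1, 0)
      u <- pgg_payoffs(H, s, r)
      K <- update_kernel(H, s, "HPC", r, delta)
      expect_equal(K[1, 2], 1 / (1 + exp(-delta * (u[2] - u[1]))))
      expect_equal(K[2, 1], 1 / (1 + exp(-delta * (u[1] - u[2]))))
    }
  }
})
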