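test_that("every generator output is a valid connected hypergraph", {
  gens <- list(
    hg_example9(),
    hg_homogeneous_weak(2, 4, 10, seed = 1),
    hg_homogeneous_weak(3, 3, 12, seed = 1),
    hg_homogeneous_weak(3, 4, 9, seed = 1),   # biregular rewiring path
    hg_ring_overlap(4, 2, 6),
    hg_dimer_chain(3),
    hg_window_ring(10, 3),
    hg_configuration_model(c(3, 2, 2, 1, 1, 1), c(4, 3, 3), seed = 1)
  )
  for (H in gens) {
    expect_s3_class(H, "hypergraph")
    expect_true(all(hyperedge_orders(H) >= 2))
    expect_true(all(hyperdegrees(H) >= 1))
    expect_handshake(H)
  }
})

test_that("homogeneous weak families are biregular with overlaps <= 1", {
  for (kg in list(c(2, 4, 10), c(3, 3, 15), c(3, 4, 9))) {
    H <- hg_homogeneous_weak(kg[1], kg[2], kg[3], seed = 7)
    expect_equal(unname(unique(hyperdegrees(H))), kg[1])
    expect_equal(unique(hyperedge_orders(H)), kg[2])
    m <- shared_edge_counts(H)
    # pairwise hyperedge overlap <= 1 <=> theta_tilde = 0
    expect_equal(hypergraph_stats(H)$theta_tilde, 0)
    expect_equal(rescaled_overlap(H), 1 / kg[2])
  }
})

test_that("infeasible weak-overlap parameters fail fast with the counting bound", {
  # N k (k - 1) = 288 shared-node pair slots > E (E - 1) = 240
  expect_error(hg_homogeneous_weak(4, 6, 16, seed = 1), "infeasible")
})

test_that("ring_overlap produces the stated structure", {
  H <- hg_ring_overlap(4, 2, 4)
  expect_equal(H$N, 8)
  expect_true(all(hyperdegrees(H) == 2))
  expect_true(all(hyperedge_orders(H) == 4))
  expect_equal(rescaled_overlap(hg_ring_overlap(4, 2, 500)), 1 / 2)
  expect_error(hg_ring_overlap(5, 2, 6), "g = 2 \\* overlap")
})

test_that("dimer_chain produces the stated structure", {
  H <- hg_dimer_chain(3)
  expect_equal(H$N, 12)
  expect_true(all(hyperdegrees(H) == 2))
  expect_true(all(hyperedge_orders(H) == 4))
  # per-hyperedge ordered overlap-square sum is 3^2 + 1^2 = 10
  m <- shared_edge_counts(H)
  B <- as.matrix(incidence_matrix(H))
  ov <- t(B) %*% B # hyperedge-pair overlap sizes
  diag(ov) <- 0
  expect_true(all(rowSums(ov^2) == 10))
  expect_equal(rescaled_overlap(hg_dimer_chain(250)), 5 / 8)
})

test_that("window_ring produces constant hyperdegree g and c_ovl 5/9", {
  H <- hg_window_ring(9, 3)
  expect_true(all(hyperdegrees(H) == 3))
  expect_true(all(hyperedge_orders(H) == 3))
  expect_equal(rescaled_overlap(hg_window_ring(1000, 3)), 5 / 9)
  expect_error(hg_window_ring(5, 3), "N >= 2")
})

test_that("configuration model realizes the requested sequences exactly", {
  k_seq <- c(5, 4, 3, 3, 2, 2, 2, 1, 1, 1)
  g_seq <- c(6, 5, 5, 4, 4)
  H <- hg_configuration_model(k_seq, g_seq, seed = 3)
  expect_equal(sort(unname(hyperdegrees(H)), decreasing = TRUE),
               sort(k_seq, decreasing = TRUE))
  expect_equal(hyperedge_orders(H), g_seq)
  # node labels are 1..N in order, so sequences match positionally
  expect_equal(unname(as.integer(hyperdegrees(H))), k_seq)

  expect_error(hg_configuration_model(c(2, 2), c(3, 3)), "must equal")
  expect_error(hg_configuration_model(c(1, 1), c(2)), NA)
})

test_that("constant configuration sequences give a homogeneous hypergraph", {
  H <- hg_configuration_model(rep(4, 30), rep(4, 30), seed = 11)
  st <- hypergraph_stats(H)
  expect_equal(st$eta_k, 1)
  expect_equal(st$eta_g, 1)
})

test_that("seeded generation is reproducible", {
  a <- hg_configuration_model(rep(3, 12), rep(4, 9), seed = 99)
  b <- hg_configuration_model(rep(3, 12), rep(4, 9), seed = 99)
  expect_identical(a$edges, b$edges)
  a2 <- hg_homogeneous_weak(2, 4, 10, seed = 5)
  b2 <- hg_homogeneous_weak(2, 4, 10, seed = 5)
  expect_identical(a2$edges, b2$edges)
})

test_that("sample_sequence respects distribution, minimum and mean", {
  expect_equal(sample_sequence("constant", 100, value = 4), rep(4L, 100))
  g <- sample_sequence("poisson", 4000, mean = 8, min_value = 2, seed = 1)
  expect_true(all(g >= 2))
  se <- sd(g) / sqrt(length(g))
  expect_lt(abs(mean(g) - 8), 3 * se)
  k <- sample_sequence("powerlaw", 2000, exponent = 2.5, min_value = 1,
                       max_value = 100, seed = 2)
  expect_true(all(k >= 1))
  expect_gt(mean(k^2) / mean(k)^2, 1) # heterogeneous by construction
})

test_that("match_sequence_total reconciles sums for the configuration model", {
  set.seed(4)
  k_seq <- sample_sequence("powerlaw", 40, exponent = 2.5, min_value = 1,
                           max_value = 10, seed = 4)
  g_seq <- sample_sequence("poisson", 20, mean = 6, min_value = 2, seed = 5)
  g_seq <- match_sequence_total(g_seq, sum(k_seq))
  expect_equal(sum(g_seq), sum(k_seq))
  expect_true(all(g_seq >= 2))
  expect_error(match_sequence_total(c(2, 2), 3), "infeasible")
})
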