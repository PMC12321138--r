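test_that("run_to_absorption respects absorbing starts and reproducibility", {
  H <- hg_small_homog()
  out <- run_to_absorption(H, "GMC", r = 1, delta = 0.1,
                           initial_state = rep(1, 6), seed = 1)
  expect_true(out$fixed_cooperation)
  expect_equal(out$steps, 0)
  out0 <- run_to_absorption(H, "HDB", r = 1, delta = 0.1,
                            initial_state = rep(0, 6), seed = 1)
  expect_false(out0$fixed_cooperation)

  a <- run_to_absorption(H, "HPC", r = 0.8, delta = 0.2,
                         initial_state = c(1, 0, 0, 0, 0, 0), seed = 31)
  b <- run_to_absorption(H, "HPC", r = 0.8, delta = 0.2,
                         initial_state = c(1, 0, 0, 0, 0, 0), seed = 31)
  expect_identical(a, b)
  expect_true(all(a$state == a$state[1])) # absorbed: monomorphic
})

test_that("a step cap triggers a non-absorption error", {
  H <- hg_window_ring(12, 3)
  expect_error(
    run_to_absorption(H, "GMC", r = 1, delta = 0,
                      initial_state = rep(c(1, 0), 6), seed = 2,
                      max_steps = 3),
    "absorption"
  )
})

test_that("neutral drift on a triangle fixes a lone cooperator 1/3 of the time", {
  H <- hg_single(3)
  fr <- simulate_fixation(H, "GIC", r = 1, delta = 0, replicates = 6000,
                          seed = 4)
  expect_gt(fr$ci_high, 1 / 3)
  expect_lt(fr$ci_low, 1 / 3)
  # single replicate yields a degenerate estimate
  fr1 <- simulate_fixation(H, "GMC", r = 1, delta = 0, replicates = 1, seed = 1)
  expect_true(fr1$rho %in% c(0, 1))
})

test_that("tidy and glance summarize fixation results", {
  H <- hg_small_homog()
  fr <- simulate_fixation(H, "HIM", r = 1.2, delta = 0.05, replicates = 500,
                          seed = 8, mutant = "defector")
  td <- tidy(fr)
  expect_equal(td$term, "rho_D")
  expect_equal(td$relative, td$estimate * 6)
  expect_gte(td$estimate, td$conf.low)
  expect_lte(td$estimate, td$conf.high)
  gl <- glance(fr)
  expect_equal(gl$mechanism, "HIM")
  expect_equal(gl$replicates, 500)
  expect_gte(gl$mean_steps, 0)
})

test_that("exact solver reproduces neutral drift 1/N for all mechanisms", {
  for (H in list(hg_example9(), hg_bowtie())) {
    for (m in mechanisms) {
      ex <- exact_fixation(H, m, r = 1, delta = 0)
      expect_equal(unname(ex["rho_C"]), 1 / H$N, tolerance = 1e-10)
      expect_equal(unname(ex["rho_D"]), 1 / H$N, tolerance = 1e-10)
    }
  }
  expect_error(exact_fixation(hg_window_ring(26, 3), "GMC", 1, 0), "N <= 12")
})

test_that("exact two-player pair-comparison matches the closed form", {
  # single order-2 hyperedge: the cooperator fixes with probability
  # 1/(1 + exp(delta)) independent of r (payoff gap is the cost)
  H <- hg_single(2)
  for (delta in c(0, 0.1, 0.5)) {
    ex <- exact_fixation(H, "HPC", r = 1.7, delta = delta)
    expect_equal(unname(ex["rho_C"]), 1 / (1 + exp(delta)), tolerance = 1e-10)
  }
})

test_that("Monte Carlo agrees with the exact solver under selection", {
  H <- hg_small_homog() # N = 6
  reps <- 20000
  cases <- expand.grid(m = mechanisms, delta = c(0, 0.05, 0.2),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    m <- cases$m[i]; delta <- cases$delta[i]
    ex <- unname(exact_fixation(H, m, r = 1.5, delta = delta)["rho_C"])
    fr <- simulate_fixation(H, m, r = 1.5, delta = delta, replicates = reps,
                            seed = 100 + i)
    se <- sqrt(ex * (1 - ex) / reps)
    expect_lt(abs(fr$rho - ex), 3 * se + 1e-12,
              label = paste("MC vs exact:", m, "delta =", delta))
  }
})

test_that("empirical_rstar rejects flat or non-bracketing setups", {
  H <- hg_window_ring(12, 3)
  expect_error(empirical_rstar(H, "GMC", delta = 0, 0.2, 1), "delta = 0")
  expect_error(
    empirical_rstar(H, "GMC", delta = 0.05, lower = 2, upper = 3,
                    replicates = 300, seed = 1, method = "bisect"),
    "straddle"
  )
})

test_that("relative fixation increases with the synergy factor", {
  H <- hg_window_ring(20, 3)
  rhos <- vapply(c(0.3, 1.2), function(r) {
    simulate_fixation(H, "GMC", r, delta = 0.25, replicates = 4000,
                      seed = 77)$rho
  }, 0)
  expect_gt(rhos[2], rhos[1])
})
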