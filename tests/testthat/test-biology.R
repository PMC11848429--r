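test_that("performer count is nearest-integer of p*M, half away from zero", {
  expect_equal(performer_count(0.5, 1000), 500)
  expect_equal(performer_count(0, 1000), 0)
  expect_equal(performer_count(0.3333, 10), 3)
  expect_equal(performer_count(0.0005, 1000), 1)  # tie rounds up
  expect_equal(performer_count(c(0.2, 0.8), c(10, 10)), c(2, 8))
})

test_that("growth vanishes at 0 and K, and suppression only subtracts", {
  expect_equal(growth_rate(1000, 1, 1000), 0)
  expect_equal(growth_rate(0, 1, 1000), 0)
  expect_equal(growth_rate(500, 1, 1000), 375)  # 500 * (1 - 0.25)
  expect_equal(growth_rate(1000, 1, 1000, form = "squared_difference"), 0)
  base <- growth_rate(100, 1, 1000)
  expect_equal(growth_rate(100, 1, 1000, alpha = 1, suppressed = TRUE),
               base - 100)
  # alpha ignored for non-suppressed species
  expect_equal(growth_rate(100, 1, 1000, alpha = 1, suppressed = FALSE),
               base)
})

test_that("fitnesses follow W0*(1+s*J) with count-weighted mean", {
  f <- fitnesses(0.5, 1000, 1, W0 = 1, s = 0.01)
  expect_equal(f$W_p, 1.01)
  expect_equal(f$W_q, 1)
  expect_equal(f$W_mean, (1.01 * 500 + 1 * 500) / 1000)
  # s = 0: byproduct-only regime, all fitnesses equal
  f0 <- fitnesses(0.3, 1000, 7, W0 = 1, s = 0)
  expect_equal(f0$W_p, f0$W_q)
  # single-genotype population: mean equals W_p
  f1 <- fitnesses(1, 1000, 2, W0 = 1, s = 0.01)
  expect_equal(f1$W_mean, f1$W_p)
  # degenerate population guard
  expect_equal(fitnesses(0.5, 0, 1, W0 = 1, s = 0.01)$W_mean, 1)
})

test_that("mutation to wild type is an order of magnitude more probable", {
  expect_equal(mutation_rates(0.1), c(m0_p = 0.1, m0_q = 0.01))
  expect_equal(mutation_rates(0), c(m0_p = 0, m0_q = 0))
  expect_equal(mutation_rates(0.2), c(m0_p = 0.2, m0_q = 0.04))
})

test_that("mutation sampling honours guards and the binomial expectation", {
  set.seed(1)
  # no mutation probability: realized fraction always 0
  d <- sample_mutations(1.01, 1, 0.5, 0.5, 0, 0)
  expect_equal(d$m_p, 0)
  expect_equal(d$m_q, 0)
  # no reproductive events: fraction 0 by the division guard
  d <- sample_mutations(1.01, 1, 0.1, 0.9, 0.1, 0.01)
  expect_equal(d$RE_p, 0L)
  expect_equal(d$m_p, 0)
  # count scaling multiplies events by M
  d <- sample_mutations(1, 1, 0.5, 0.5, 0.1, 0.01,
                        re_scale = "count", M = 1000)
  expect_equal(d$RE_p, 500L)
  expect_true(d$same_p <= d$RE_p)
  expect_equal(d$m_p, (d$RE_p - d$same_p) / d$RE_p)
  # binomial oracle: mean realized fraction over 1e4 single-event draws
  set.seed(42)
  m <- replicate(1e4, sample_mutations(1, 1, 1, 0, 0.1, 0.01)$m_p)
  se <- sqrt(0.1 * 0.9 / 1e4)
  expect_lt(abs(mean(m) - 0.1), 3 * se)
})

test_that("frequency derivatives: fixation and neutrality give zero drift", {
  # fixation: W_mean = W_p, no mutation
  fd <- frequency_derivatives(1.01, 1, 1.01, 0, 0)
  expect_equal(fd$dp, 0)
  # neutrality (s = 0): all fitnesses equal at any p
  f <- fitnesses(0.37, 1000, 5, W0 = 1, s = 0)
  fd <- frequency_derivatives(f$W_p, f$W_q, f$W_mean, 0, 0)
  expect_equal(fd$dp, 0)
  # mutation contributions cancel between dp and dq
  fd1 <- frequency_derivatives(1.01, 1, 1.005, 0.1, 0.01)
  fd0 <- frequency_derivatives(1.01, 1, 1.005, 0, 0)
  expect_equal((fd1$dp + fd1$dq) - (fd0$dp + fd0$dq), 0)
  # invalid fitness state is an error
  expect_error(frequency_derivatives(1, 1, 0, 0, 0), "W_mean")
})

test_that("selection direction follows the sign of s at fixed substrate", {
  # deterministic runs with mutation off and J pinned by heavy influx
  for (s_val in c(0.02, -0.02)) {
    par <- cbv_params(s = s_val, m0 = 0, sigma_bar = 0, Xvar0 = 0)
    sim <- run_simulation(par, run_config(n_steps = 300, record_every = 1))
    p_series <- sim$series$p_A
    diffs <- diff(p_series)
    if (s_val > 0) expect_true(all(diffs >= -1e-12)) else
      expect_true(all(diffs <= 1e-12))
  }
})

test_that("frequencies stay in [0,1] with p + q = 1 along stochastic runs", {
  sim <- run_simulation(cbv_params(), run_config(n_steps = 500, seed = 7))
  pcols <- as.matrix(sim$series[, c("p_A", "p_B", "p_C", "p_D")])
  expect_true(all(pcols >= 0 & pcols <= 1))
  expect_true(all(as.matrix(
    sim$series[, c("M_A", "M_B", "M_C", "M_D")]) >= 0))
})
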