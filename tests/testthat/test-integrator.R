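test_that("reaction partial matches a central finite difference", {
  p <- cbv_params()
  # flat branch of the bioavailability cap
  expect_equal(reaction_partial(1, 2000, p$Rmax, p$Km, p$rn_bar, p$omega),
               0)
  expect_equal(reaction_partial(0, 500, p$Rmax, p$Km, p$rn_bar, p$omega),
               0)
  set.seed(5)
  for (k in 1:20) {
    J <- runif(1, 0.1, 5)
    n <- runif(1, 10, 900)  # interior of the capped region
    h <- 1e-4
    fd <- (reaction_rate(J, n + h, p$Rmax, p$Km, p$rn_bar, p$omega) -
           reaction_rate(J, n - h, p$Rmax, p$Km, p$rn_bar, p$omega)) /
      (2 * h)
    an <- reaction_partial(J, n, p$Rmax, p$Km, p$rn_bar, p$omega)
    expect_lt(abs(an - fd) / abs(fd), 1e-6)
  }
})

test_that("byproduct-flux partials match central finite differences", {
  set.seed(6)
  for (k in 1:20) {
    XA <- runif(1, 0.05, 4); XB <- runif(1, 0.05, 4)
    Xv0 <- runif(1, 0.2, 1)
    h <- 1e-5
    an <- xvar_partials(XA, XB, Xv0, 1, 1)
    fdA <- (xvar_flux(XA + h, XB, Xv0, 1, 1) -
            xvar_flux(XA - h, XB, Xv0, 1, 1)) / (2 * h)
    fdB <- (xvar_flux(XA, XB + h, Xv0, 1, 1) -
            xvar_flux(XA, XB - h, Xv0, 1, 1)) / (2 * h)
    expect_lt(abs(an$dXA - fdA) / abs(fdA), 1e-6)
    expect_lt(abs(an$dXB - fdB) / abs(fdB), 1e-6)
  }
})

test_that("variance terms: fixation limit, arithmetic, Monte-Carlo oracle", {
  # no variance at fixation without mutation
  v <- variance_terms(1, 1000, 1.01, 1, RE_p = 1, m0_p = 0)
  expect_equal(v$VAR_np, 0)
  v <- variance_terms(0, 1000, 1.01, 1, RE_p = 0, m0_p = 0)
  expect_equal(v$VAR_np, 0)
  # binomial variance of the mutation fraction
  expect_equal(variance_terms(0.5, 1000, 1.01, 1, 1, 0.1)$VAR_p, 0.09)
  expect_equal(variance_terms(0.5, 1000, 1.01, 1, 4, 0.1)$VAR_p,
               0.09 / 4)
  # Monte-Carlo oracle: empirical variance of the realized fraction
  set.seed(10)
  draws <- replicate(1e5, sample_mutations(1, 1, 1, 0, 0.1, 0.01)$m_p)
  expect_lt(abs(var(draws) - 0.09) / 0.09, 0.05)
})

test_that("diffusion terms vanish at fixation and respect the topology", {
  par <- cbv_params(m0 = 0)
  st <- init_state(par, run_config(init = list(p = c(1, 1, 1, 1))))
  g <- diffusion_terms(st, par)
  expect_equal(unname(g$g_S), rep(0, 4))
  expect_equal(g$g_J, rep(0, 3))
  expect_equal(g$g_Xmain, 0)
  # J3 noise combines only reactions C and D; J2 only A, B, D
  par <- cbv_params()
  st <- init_state(par, run_config(init = list(p = c(1, 1, 0.5, 0.5),
                                               M = rep(1000, 4))))
  par0 <- cbv_params(m0 = 0)
  g <- diffusion_terms(st, par0)  # m0 = 0: only VAR_S contributes
  expect_equal(unname(g$g_R[c("A", "B")]), c(0, 0))
  expect_equal(g$g_J[3], sqrt(g$g_R[["C"]]^2 + g$g_R[["D"]]^2))
  expect_equal(g$g_J[1], g$g_R[["C"]])
  expect_equal(g$g_J[2], g$g_R[["D"]])
})

test_that("deterministic runs are bit-identical across seeds", {
  par <- cbv_params(sigma_bar = 0)
  s1 <- run_simulation(par, run_config(n_steps = 200, seed = 1))
  s2 <- run_simulation(par, run_config(n_steps = 200, seed = 999))
  expect_identical(s1$series[, -1], s2$series[, -1])
})

test_that("fixed-seed stochastic runs reproduce bit-for-bit", {
  par <- cbv_params()
  s1 <- run_simulation(par, run_config(n_steps = 200, seed = 42))
  s2 <- run_simulation(par, run_config(n_steps = 200, seed = 42))
  expect_identical(s1$series, s2$series)
  s3 <- run_simulation(par, run_config(n_steps = 200, seed = 43))
  expect_false(identical(s1$series, s3$series))
})

test_that("engine agrees with the module-composed reference stepper", {
  # deterministic path, multi-step
  par <- cbv_params(sigma_bar = 0, tau_X = 3)
  st_ref <- reference_trajectory(par, 50)
  st_eng <- init_state(par, run_config())
  for (k in 1:50) st_eng <- em_step(st_eng, par)
  expect_equal(state_vec(st_eng), state_vec(st_ref), tolerance = 1e-12)
  # stochastic path: same seed, same draw order, same trajectory
  for (seed in c(2, 17)) {
    par <- cbv_params(tau_X = 3)
    st_ref <- reference_trajectory(par, 40, seed = seed)
    st_eng <- init_state(par, run_config())
    set.seed(seed)
    for (k in 1:40) st_eng <- em_step(st_eng, par)
    expect_equal(state_vec(st_eng), state_vec(st_ref), tolerance = 1e-10)
  }
  # run_simulation is the same engine: final state matches em_step loop
  sim <- run_simulation(cbv_params(tau_X = 3),
                        run_config(n_steps = 40, seed = 17,
                                   record_every = 40))
  expect_equal(state_vec(sim$final), state_vec(st_eng), tolerance = 1e-12)
})

test_that("tau = 1 stepping equals a single-clock Euler step", {
  par <- cbv_params(sigma_bar = 0, tau_J = 1, tau_X = 1)
  st <- init_state(par, run_config())
  # plain single-clock Euler: identical dt for every subsystem
  ref <- reference_step(st, par, dt_bio = 1)
  eng <- em_step(st, par, dt_bio = 1)
  expect_equal(state_vec(eng), state_vec(ref), tolerance = 1e-12)
})

test_that("halving dt halves the one-step deterministic drift exactly", {
  par <- cbv_params(sigma_bar = 0)
  st <- init_state(par, run_config())
  d1 <- state_vec(em_step(st, par, dt_bio = 1))[1:16] - state_vec(st)[1:16]
  d2 <- state_vec(em_step(st, par, dt_bio = 0.5))[1:16] -
    state_vec(st)[1:16]
  expect_equal(d1, 2 * d2, tolerance = 1e-12)
})

test_that("abiotic relaxation: J converges to Fin0/Fout0 with alpha 0", {
  par <- cbv_params(sigma_bar = 0, m0 = 0)
  run <- run_config(n_steps = 200, record_every = 1,
                    init = list(p = c(0, 0, 0, 0), J = c(0.2, 3, 0)))
  sim <- run_simulation(par, run)
  fin <- final_row(sim)
  expect_lt(max(abs(c(fin$J1, fin$J2, fin$J3) - 1)), 1e-6)
  expect_equal(max(sim$series$alpha), 0)
  expect_equal(nrow(sim$series), 201)  # initial state + one row per step
})

test_that("no byproduct efficiency means no suppression, deterministically", {
  par <- cbv_params(sigma_bar = 0, Xvar0 = 0)
  sim <- run_simulation(par, run_config(n_steps = 2000, record_every = 10))
  expect_equal(max(sim$series$alpha), 0)
  expect_equal(max(sim$series$X), 1)  # pinned at the abiotic state
})
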