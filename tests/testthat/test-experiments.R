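test_that("timescale contrast runs share seed and differ only in tau_X", {
  res <- run_single(cbv_params(sigma_bar = 0), run_config(n_steps = 100),
                    tau_X_values = c(5, 15))
  expect_named(res, c("tau_X=5", "tau_X=15"))
  expect_equal(res[[1]]$params$tau_X, 5)
  expect_equal(res[[2]]$params$tau_X, 15)
  expect_equal(res[[1]]$seed, res[[2]]$seed)
  # the biology and J-cycle clocks are unaffected by tau_X before any
  # X-cycle influence feeds back
  expect_equal(res[[1]]$series$p_A, res[[2]]$series$p_A)
})

test_that("replicate seeds are a pure function of cell and replicate", {
  g <- sweep_grid(list(s = c(0, 0.02), m0 = c(0.05, 0.2)),
                  replicates = 3, base_seed = 7)
  run <- run_config(n_steps = 150)
  sw1 <- run_sweep(cbv_params(), g, run)
  sw2 <- run_sweep(cbv_params(), g, run)
  expect_identical(sw1$replicates, sw2$replicates)
  # re-running a single cell in isolation reproduces its replicates
  g1 <- sweep_grid(list(s = c(0, 0.02), m0 = c(0.05, 0.2)),
                   replicates = 3, base_seed = 7)
  cell3 <- sw1$replicates[sw1$replicates$cell == 3, ]
  p2 <- cbv_params()
  p2$s <- cell3$s[1]; p2$m0 <- cell3$m0[1]
  for (ri in 1:3) {
    run2 <- run
    run2$seed <- cell3$seed[ri]
    run2$record_every <- sw1$run$record_every
    sim <- run_simulation(p2, run2)
    expect_equal(final_row(sim)$cbv_AB_norm, cell3$cbv_AB_norm[ri])
    expect_equal(final_row(sim)$X, cell3$X[ri])
  }
})

test_that("cell means recompute exactly from retained replicate finals", {
  g <- sweep_grid(list(s = c(0, 0.03), m0 = c(0.1)), replicates = 4,
                  base_seed = 2)
  sw <- run_sweep(cbv_params(), g, run_config(n_steps = 150))
  expect_equal(nrow(sw$cells), 2)
  expect_equal(sw$cells$n, c(4L, 4L))
  for (ci in sw$cells$cell) {
    d <- sw$replicates[sw$replicates$cell == ci, ]
    expect_equal(sw$cells$mean_J[sw$cells$cell == ci], mean(d$mean_J))
    expect_equal(sw$cells$alpha[sw$cells$cell == ci], mean(d$alpha))
    expect_equal(sw$cells$cbv_AB_norm[sw$cells$cell == ci],
                 mean(d$cbv_AB_norm))
    # shares sum to one per replicate
    expect_equal(d$cbv_AB_norm + d$cbv_CDB_norm, rep(1, nrow(d)))
  }
})

test_that("deterministic single-replicate sweeps are reproducible", {
  g <- sweep_grid(list(s = c(0.01), m0 = c(0.1, 0.2)), replicates = 1)
  run <- run_config(n_steps = 100, sigma_bar = 0)
  sw1 <- run_sweep(cbv_params(), g, run)
  sw2 <- run_sweep(cbv_params(), g, run)
  expect_identical(sw1$cells, sw2$cells)
})

test_that("correlation analysis: exact line, degenerate cells, pooling", {
  # synthetic finals lying exactly on a rising line: r = 1
  d <- data.frame(cell = rep(1:2, each = 5),
                  alpha = rep(seq(0, 1, length.out = 5), 2))
  d$cbv_AB_norm <- 0.2 + 0.6 * d$alpha
  cr <- correlate_sweep(d)
  expect_equal(cr$pooled$r, 1)
  expect_equal(cr$pooled$slope, 0.6)
  expect_equal(cr$pooled$intercept, 0.2)
  expect_true(all(cr$cells$defined))
  expect_equal(cr$cells$r, c(1, 1))
  # all-identical finals in a cell: flagged undefined, not an error
  d2 <- data.frame(cell = c(1, 1, 1, 2, 2, 2),
                   alpha = c(0, 0, 0, 0, 0.5, 1),
                   cbv_AB_norm = c(0.4, 0.5, 0.6, 0.3, 0.5, 0.7))
  cr2 <- correlate_sweep(d2)
  expect_false(cr2$cells$defined[1])
  expect_true(is.na(cr2$cells$r[1]))
  expect_true(cr2$cells$defined[2])
  # fewer than 2 replicates: undefined
  d3 <- data.frame(cell = 1, alpha = 0.3, cbv_AB_norm = 0.6)
  expect_false(correlate_sweep(d3)$cells$defined)
  # zero pooled variance: NA result rather than error
  d4 <- data.frame(cell = rep(1, 4), alpha = rep(0, 4),
                   cbv_AB_norm = runif(4))
  expect_true(is.na(correlate_sweep(d4)$pooled$r))
})

test_that("standard sweep rows encode the three boundary conditions", {
  sw <- standard_sweeps(n_axis = 3, replicates = 2)
  expect_named(sw, c("no_feedback", "feedback", "feedback_magnitude"))
  expect_equal(sw$no_feedback$fixed$Xvar0, 0)
  expect_equal(sw$feedback$fixed, list(Xvar0 = 1, alpha0 = 1))
  expect_equal(names(sw$feedback_magnitude$axes), c("Xvar0", "alpha0"))
  expect_equal(range(sw$no_feedback$axes$s), c(0, 0.05))
  expect_equal(range(sw$no_feedback$axes$m0), c(0.01, 0.3))
})
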