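test_that("origin is a fixed point and one Euler step matches hand arithmetic", {
  p <- msi_params()
  s0 <- msi_state0(20)
  s1 <- euler_step(s0, zero_inputs(), p)
  for (f in names(s1)) expect_equal(s1[[f]], numeric(20), info = f)
  # uniform bimodal unit inputs: p_sen moves by dt * beta_d * 1 in one step
  inp <- msi_inputs(rep(1, 20), rep(1, 20), numeric(20), numeric(20))
  s1 <- euler_step(s0, inp, p)
  expect_equal(s1$p_sen, rep(p$dt * p$beta_d, 20))
  # and r by dt * beta_d * EX with EX = 2
  expect_equal(s1$r, rep(p$dt * 2, 20))
})

test_that("non-finite states are rejected with the population named", {
  p <- msi_params()
  s <- msi_state0(20)
  s$q_m[3] <- Inf
  inp <- aligned_condition("bimodal_full", 0.5)
  expect_error(euler_step(s, inp, p), "q_m")
})

test_that("zero inputs give a silent equilibrium and decaying state norm", {
  p <- msi_params(n_steps = 500)
  res <- simulate(zero_inputs(), p)
  expect_equal(res$sc_rate, numeric(20))
  expect_equal(res$residual, 0)
  # pure leak in the SC core (r, p_sen, p_pool): the norm decays monotonically.
  # From a generic full state the cortical veto transiently pushes q_m and the
  # S2 populations below zero before everything relaxes, so monotonicity is a
  # property of the leak-only configuration, while convergence to the silent
  # state holds from any bounded start.
  s <- msi_state0(20)
  for (f in c("r", "p_sen", "p_pool")) s[[f]] <- rep(0.5, 20)
  norms <- sqrt(sum(unlist(s)^2))
  for (i in 1:300) {
    s <- euler_step(s, zero_inputs(), p)
    norms <- c(norms, sqrt(sum(unlist(s)^2)))
  }
  expect_true(all(diff(norms) < 0))
  # full-state relaxation carries a slow t*exp(-t) mode (the S2 populations
  # are resonantly forced by the decaying S1 rates), so give it 8 time
  # constants to fall below 5% of the starting norm
  s_full <- msi_state0(20)
  for (f in names(s_full)) s_full[[f]] <- rep(0.5, 20)
  start_norm <- sqrt(sum(unlist(s_full)^2))
  for (i in 1:8000) s_full <- euler_step(s_full, zero_inputs(), p)
  expect_lt(sqrt(sum(unlist(s_full)^2)), 0.05 * start_norm)
})

test_that("coincidence detector is exactly silent for unimodal input", {
  p <- msi_params(n_steps = 1000)
  for (cnd in c("unimodal_audio", "unimodal_visual")) {
    res <- simulate(aligned_condition(cnd, 0.8), p)
    expect_identical(res$final_state$p_sen, numeric(20))
  }
})

test_that("p_sen equilibrium matches the closed-form fixed point", {
  # algebraic oracle: p* = beta_d * S / (alpha_sen + S) with S = s_a * s_v.
  # Convergence goes as exp(-(alpha_sen + S) t), so the default 4000-step
  # presentation reaches the 1e-3 band for products S >= ~0.5; weaker products
  # are checked against the same oracle at a transient-matched tolerance.
  p <- msi_params()
  cases <- list(c(1, 1), c(0.9, 0.8), c(0.8, 0.5))
  for (cs in cases) {
    inp <- msi_inputs(rep(cs[1], 20), rep(cs[2], 20), numeric(20), numeric(20))
    res <- simulate(inp, p)
    s_prod <- cs[1] * cs[2]
    fixed_point <- p$beta_d * s_prod / (p$alpha_sen + s_prod)
    transient <- fixed_point * exp(-(p$alpha_sen + s_prod) * p$dt * p$n_steps)
    expect_lt(max(abs(res$final_state$p_sen - fixed_point)),
              max(1e-3, 2 * transient))
  }
  inp1 <- msi_inputs(rep(1, 20), rep(1, 20), numeric(20), numeric(20))
  expect_lt(max(abs(simulate(inp1, p)$final_state$p_sen - 0.5)), 1e-3)
})

test_that("drive terms decompose as excitation, modulation, inhibition", {
  p <- msi_params()
  inp <- aligned_condition("bimodal_full", 0.5)
  d0 <- compute_drives(msi_state0(20), inp, p)
  expect_equal(d0$EX, inp$s_a + inp$s_v)
  expect_equal(d0$MOD, numeric(20))
  expect_equal(d0$INH, numeric(20))
  # at the converged state the modulatory drive peaks at the stimulus
  res <- simulate(inp, p)
  d1 <- compute_drives(res$final_state, inp, p)
  expect_gt(d1$MOD[9], 0)
  expect_equal(which.max(d1$MOD) - 1L, 8L)
  bad <- msi_inputs(numeric(10), numeric(10), numeric(10), numeric(10))
  expect_error(compute_drives(msi_state0(20), bad, p), "n_neurons")
})

test_that("membrane potentials and rates stay bounded over the integration", {
  p <- msi_params()
  res <- simulate(aligned_condition("bimodal_full", 1), p,
                  trajectory_stride = 400L)
  for (snap in res$trajectory) {
    expect_true(all(abs(unlist(snap)) <= 10))
  }
  expect_true(all(res$sc_rate >= 0 & res$sc_rate <= 1))
})

test_that("bimodal aligned stimulation peaks at the stimulus location", {
  res <- simulate(aligned_condition("bimodal_full", 0.5), msi_params())
  expect_equal(which.max(res$sc_rate) - 1L, 8L)
  expect_lt(res$residual, 1e-4)
})

test_that("cross-modal gating requires both cortical inputs", {
  p <- msi_params()
  for (I in c(0.2, 0.6, 1)) {
    both <- simulate(aligned_condition("bimodal_full", I), p)
    one <- simulate(aligned_condition("bimodal_ctx_audio_only", I), p)
    g_both <- max(activation_g(both$final_state$q_m))
    g_one <- max(activation_g(one$final_state$q_m))
    expect_gt(g_both, 10 * max(g_one, 1e-12))
  }
})

test_that("halving the step size leaves the equilibrium unchanged", {
  p <- msi_params()
  p2 <- msi_params(dt = p$dt / 2, n_steps = p$n_steps * 2L)
  inp <- aligned_condition("bimodal_full", 0.5)
  r1 <- simulate(inp, p)
  r2 <- simulate(inp, p2)
  expect_lt(max(abs(r1$sc_rate - r2$sc_rate)), 1e-3)
})

test_that("batched integration reproduces single runs column by column", {
  p <- msi_params(n_steps = 600)
  inputs <- list(aligned_condition("bimodal_full", 0.3),
                 aligned_condition("unimodal_audio", 0.8),
                 zero_inputs())
  out <- simulate_batch(inputs, p)
  for (k in seq_along(inputs)) {
    single <- simulate(inputs[[k]], p)
    expect_equal(out$sc_rate[, k], single$sc_rate, tolerance = 1e-12)
    expect_equal(out$membrane[, k], single$final_state$r, tolerance = 1e-12)
  }
})
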