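test_that("rate encoding clips, seeds and matches the binomial count", {
  expect_identical(encode_rate(0, 100, seed = 1)$spikes, integer(100))
  full <- encode_rate(1.4, 50, seed = 1)
  expect_identical(full$spikes, rep(1L, 50))
  expect_true(full$clipped)
  tr <- encode_rate(0.25, 10000, seed = 7)
  expect_false(tr$clipped)
  count <- sum(tr$spikes)
  expect_lt(abs(count - 2500), 3 * sqrt(10000 * 0.25 * 0.75))
  expect_identical(encode_rate(0.25, 10000, seed = 7)$spikes, tr$spikes)
})

test_that("coincidence multiplication matches the product of rates", {
  a <- encode_rate(0.5, 10000, seed = 1, stream = 1)
  b <- encode_rate(0.5, 10000, seed = 1, stream = 2)
  ab <- and_multiply(a, b)
  se <- sqrt(0.25 * 0.75 / 10000)
  expect_lt(abs(ab$rate - 0.25), 3 * se)
  z <- encode_rate(0, 10000, seed = 2)
  expect_identical(and_multiply(a, z)$spikes, integer(10000) + 0L)
  short <- encode_rate(0.5, 100, seed = 3)
  expect_error(and_multiply(a, short), "equal window")
  # general products within binomial error
  for (pq in list(c(0.3, 0.7), c(0.9, 0.2))) {
    x <- encode_rate(pq[1], 10000, seed = 4, stream = 1)
    y <- encode_rate(pq[2], 10000, seed = 4, stream = 2)
    pe <- pq[1] * pq[2]
    expect_lt(abs(and_multiply(x, y)$rate - pe),
              3 * sqrt(pe * (1 - pe) / 10000) + 0.01)
  }
})

test_that("compiled graph contains the expected elementary operations", {
  g <- compile_model(msi_params())
  counts <- op_counts(g)
  expect_identical(unname(counts["ode_root"]), 8L) # one root per equation
  expect_identical(unname(counts["sigmoid"]), 1L)
  expect_gt(counts["splitter"], 0L)
  kinds <- vapply(g$nodes, `[[`, character(1), "kind")
  # the modulatory interneuron's shunting factor is an add_const node
  expect_identical(g$nodes$qm_inh_fac$kind, "add_const")
  # the SC excitation product multiplies conductance, input sum and feedback
  expect_setequal(g$nodes$r_exc$inputs, c("r_compl", "ex_half", "fb_scaled"))
  expect_identical(g$nodes$r_exc$kind, "mul_vars")
  # the coincidence drive multiplies the two sensory trains
  expect_true("sasv_prod" %in% names(g$nodes))
  # nodes are topologically ordered: every input precedes its consumer
  seen <- character(0)
  for (nd in g$nodes) {
    expect_true(all(nd$inputs %in% seen), info = nd$name)
    seen <- c(seen, nd$name)
  }
})

test_that("convolution and complement nodes reproduce their algebraic values", {
  p <- msi_params()
  g <- compile_model(p)
  kernels <- lapply(model_kernels(p), unclass)
  W <- 10000L; n <- p$n_neurons
  set.seed(31)
  rng <- stats::runif
  clipstat <- list(add = function(...) NULL)
  # feed a known Bernoulli field through the lateral convolution node
  probs <- gaussian_input(stimulus_spec(8, 2, 0.6), n)
  spikes <- (matrix(runif(W * n), W, n) <
               matrix(probs, W, n, byrow = TRUE)) * 1
  conv_nd <- g$nodes$inh_pool_conv
  out <- msinet:::eval_node(conv_nd, list(g_pool = spikes), list(), kernels,
                            W, n, rng, clipstat)
  expected <- as.numeric(kernels$lateral %*% probs)
  se <- sqrt(pmax(expected * (1 - expected), 0.25) / W)
  expect_true(all(abs(colMeans(out) - expected) < 3 * se + 0.005))
  # complement node: exact tickwise NOT
  compl_nd <- g$nodes$r_compl
  nout <- msinet:::eval_node(compl_nd, list(r_enc = spikes), list(), kernels,
                             W, n, rng, clipstat)
  expect_equal(nout, 1 - spikes)
})

test_that("spiking backend is silent on zero input and reproducible", {
  z <- msi_inputs(numeric(20), numeric(20), numeric(20), numeric(20))
  res <- simulate_spiking(z, msi_params(), ticks_per_step = 8, seed = 4,
                          n_steps = 40)
  expect_equal(max(unlist(res$rates)), 0)
  p13 <- msi_params(n_neurons = 13)
  inp <- build_condition_inputs(
    condition_spec("bimodal_full", audio = stimulus_spec(6, 1, 0.4),
                   visual = stimulus_spec(6, 1, 0.4)), 13)
  s1 <- simulate_spiking(inp, p13, ticks_per_step = 16, seed = 9, n_steps = 50)
  s2 <- simulate_spiking(inp, p13, ticks_per_step = 16, seed = 9, n_steps = 50)
  expect_identical(s1$states, s2$states)
  s3 <- simulate_spiking(inp, p13, ticks_per_step = 16, seed = 10, n_steps = 50)
  expect_false(identical(s1$states, s3$states))
})

test_that("spiking equilibria track the rate model across populations", {
  p <- msi_params(n_neurons = 13)
  inp <- build_condition_inputs(
    condition_spec("bimodal_full", audio = stimulus_spec(6, 1, 0.4),
                   visual = stimulus_spec(6, 1, 0.4)), 13)
  cmp <- spike_compare(inp, p, ticks_per_step = 128, seed = 5, n_steps = 1500)
  # the membrane integrates ~1000 windows, so the window-level binomial error
  # (~0.04 at 128 ticks) is attenuated well below 0.03 at the equilibrium
  expect_lt(max(cmp$abs_error), 0.03)
  expect_lt(mean(cmp$abs_error), 0.01)
  expect_setequal(unique(cmp$population),
                  c("r", "p_sen", "p_pool", "q_m",
                    "q_s1a", "q_s2a", "q_s1v", "q_s2v"))
})
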