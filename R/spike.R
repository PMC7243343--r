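#' Encode a real value as a stochastic spike train
#'
#' Spike-rate coding: a value in `[0, 1]` becomes the per-tick firing
#' probability of a Bernoulli spike train; values outside `[0, 1]` are clipped
#' before encoding. The empirical rate of the train converges to the encoded
#' value as the window grows.
#'
#' @param value Real value to encode.
#' @param ticks Window length (>= 1).
#' @param seed Integer seed (with an optional `stream`) for the train.
#' @param stream Integer stream index, default 0.
#' @return An `msi_spike_trace`: integer 0/1 vector `spikes` plus its mean
#'   `rate` and the `clipped` flag.
#' @export
#' @examples
#' tr <- encode_rate(0.25, ticks = 1000, seed = 7)
#' tr$rate
encode_rate <- function(value, ticks, seed = 1L, stream = 0L) {
  stopifnot(ticks >= 1)
  p <- min(max(value, 0), 1)
  rng <- rng_stream(seed, stream)
  spikes <- as.integer(rng(as.integer(ticks)) < p)
  structure(list(spikes = spikes, rate = mean(spikes),
                 clipped = (value < 0 || value > 1)),
            class = "msi_spike_trace")
}

#' Multiply two spike trains by coincidence (logical AND)
#'
#' Tickwise AND of two spike trains: for independent trains the expected
#' output rate is the product of the input rates, which is how the backend
#' realizes every product in the dynamics. Correlated operand trains bias the
#' product (AND of a train with itself returns the train, not its square), so
#' operands must come from independent encoding streams.
#'
#' @param a,b `msi_spike_trace` objects with equal window lengths.
#' @return An `msi_spike_trace` of the same length.
#' @export
and_multiply <- function(a, b) {
  stopifnot(inherits(a, "msi_spike_trace"), inherits(b, "msi_spike_trace"))
  if (length(a$spikes) != length(b$spikes)) {
    stop("spike trains must have equal window lengths", call. = FALSE)
  }
  spikes <- a$spikes * b$spikes
  structure(list(spikes = spikes, rate = mean(spikes), clipped = FALSE),
            class = "msi_spike_trace")
}

# --- operation graph ---------------------------------------------------------

op_node <- function(name, kind, inputs = character(0), params = list(),
                    usage = "") {
  list(name = name, kind = kind, inputs = inputs, params = params,
       usage = usage)
}

#' Compile the rate model into an elementary-operation graph
#'
#' Decomposes the eight membrane-potential equations into the elementary
#' operations a single hardware neuron can perform: adding/subtracting/
#' multiplying by a constant (`add_const`, `sub_const`, `mul_const`), weighted
#' sums and products of variables (`add_vars`, `mul_vars`), convolution over
#' channels (`convolution`), the sigmoidal transfer function (`sigmoid`),
#' ODE-evaluating root neurons (`ode_root`) and pass-through `splitter`
#' copies. Each node is replicated across all feature channels. Because spike
#' rates only represent `[0, 1]`, quantities with a larger range are scaled
#' down at their node and the weights of downstream root neurons are raised to
#' compensate: the excitatory sums `S^a + S^v` and `C^a + C^v` and the total
#' inhibition carry a factor 1/2; the broad feedback-path convolutions are
#' divided by their maximal row sum `sigma_m * sqrt(2*pi)`; the feedback
#' factor `(1 + lambda * MOD)` is divided by its maximum; the modulatory
#' membrane `q_m` (saturation `beta_m = 2`) is kept at half scale; and the
#' shunting inhibition factors are divided by their maxima
#' (`gamma_m + 2 kappa_m`, `gamma_s2 + 1`).
#'
#' @param params An `msi_params` object.
#' @return An `msi_opgraph`: topologically ordered list of operation nodes
#'   plus the root bookkeeping (population, time constant, leak, state scale,
#'   drive weights).
#' @export
compile_model <- function(params = msi_params()) {
  validate_msi_params(params)
  p <- params
  qm_inh_max <- p$gamma_m + 2 * p$kappa_m
  s2_inh_max <- p$gamma_s2 + 1
  # max row sum of the unit-amplitude modulatory kernel and the resulting
  # bound of the feedback factor (1 + lambda * MOD)
  s_mod <- p$sigma_mod * sqrt(2 * pi)
  fb_max <- 1 + p$lam * s_mod
  nodes <- list(
    # external input fields, encoded at their native [0,1] scale
    op_node("in_sa", "input", params = list(field = "s_a"), usage = "S^a"),
    op_node("in_sv", "input", params = list(field = "s_v"), usage = "S^v"),
    op_node("in_ca", "input", params = list(field = "c_a"), usage = "C^a"),
    op_node("in_cv", "input", params = list(field = "c_v"), usage = "C^v"),
    op_node("split_sa", "splitter", "in_sa", usage = "S^a copy for p_sen"),
    op_node("split_sv", "splitter", "in_sv", usage = "S^v copy for p_sen"),
    op_node("split_ca", "splitter", "in_ca", usage = "C^a copy for S1/S2"),
    op_node("split_cv", "splitter", "in_cv", usage = "C^v copy for S1/S2"),
    op_node("ex_half", "add_vars", c("in_sa", "in_sv"),
            list(weights = c(0.5, 0.5)), usage = "(S^a+S^v)/2"),
    op_node("cc_half", "add_vars", c("in_ca", "in_cv"),
            list(weights = c(0.5, 0.5)), usage = "(C^a+C^v)/2"),

    # SC neuron r
    op_node("r_enc", "mul_const", params = list(root = "r", mult = 1),
            usage = "r_i as rate"),
    op_node("r_enc2", "mul_const", params = list(root = "r", mult = 1),
            usage = "r_i as rate (inhibition branch)"),
    op_node("r_compl", "sub_const", "r_enc", list(const = p$beta_d),
            usage = "(beta_d - r_i)"),
    op_node("g_qm", "mul_const", params = list(root = "q_m", mult = 2),
            usage = "g(q_m) from half-scale membrane"),
    op_node("mod_conv", "convolution", "g_qm",
            list(kernel = "modulatory", scale = s_mod),
            usage = "MOD_i / s_mod"),
    op_node("fb_scaled", "add_const", "mod_conv",
            list(const = 1 / fb_max, mult = p$lam * s_mod / fb_max),
            usage = "(1 + lambda MOD) / (1 + lambda s_mod)"),
    op_node("r_exc", "mul_vars", c("r_compl", "ex_half", "fb_scaled"),
            usage = "(beta_d - r) EX (1+lambda MOD) / (2 fb_max)"),
    op_node("g_pool", "mul_const", params = list(root = "p_pool", mult = 1),
            usage = "g(p_pool)"),
    op_node("inh_pool_conv", "convolution", "g_pool",
            list(kernel = "lateral", scale = 1), usage = "sum K g(p_pool)"),
    op_node("g_sen", "mul_const", params = list(root = "p_sen",
                                                mult = p$slope_g_sen),
            usage = "g_sen(p_sen), slope k"),
    op_node("inh_sen_conv", "convolution", "g_sen",
            list(kernel = "lateral", scale = 1), usage = "sum K g_sen(p_sen)"),
    op_node("inh_half", "add_vars", c("inh_pool_conv", "inh_sen_conv"),
            list(weights = c(0.5, 0.5)), usage = "INH/2"),
    op_node("r_inh", "mul_vars", c("r_enc2", "inh_half"), usage = "r INH / 2"),
    op_node("root_r", "ode_root", c("r_exc", "r_inh"),
            list(root = "r", tau = p$tau_d, alpha = p$alpha_d,
                 weights = c(2 * fb_max, -2 * p$kappa_r), state_scale = 1),
            usage = "dr/dt"),
    op_node("h_r", "sigmoid", params = list(root = "r", slope = p$slope_h),
            usage = "h(r_i)"),

    # coincidence detector p_sen
    op_node("psen_enc", "mul_const", params = list(root = "p_sen", mult = 1)),
    op_node("psen_compl", "sub_const", "psen_enc", list(const = p$beta_d),
            usage = "(beta_d - p_sen)"),
    op_node("sasv_prod", "mul_vars", c("split_sa", "split_sv"),
            usage = "S^a S^v"),
    op_node("psen_drive", "mul_vars", c("psen_compl", "sasv_prod")),
    op_node("root_p_sen", "ode_root", "psen_drive",
            list(root = "p_sen", tau = p$tau_sen, alpha = p$alpha_sen,
                 weights = 1, state_scale = 1),
            usage = "dp_sen/dt"),

    # normalization pool p_pool
    op_node("pool_conv", "convolution", "h_r",
            list(kernel = "lateral", scale = 1), usage = "sum K h(r)"),
    op_node("ppool_enc", "mul_const", params = list(root = "p_pool", mult = 1)),
    op_node("ppool_compl", "sub_const", "ppool_enc", list(const = p$beta_d)),
    op_node("ppool_drive", "mul_vars", c("ppool_compl", "pool_conv")),
    op_node("root_p_pool", "ode_root", "ppool_drive",
            list(root = "p_pool", tau = p$tau_d, alpha = p$alpha_d,
                 weights = 1, state_scale = 1),
            usage = "dp_pool/dt"),

    # modulatory interneuron q_m, membrane stored at half scale
    op_node("qm_enc", "mul_const", params = list(root = "q_m", mult = 1)),
    op_node("qm_enc2", "mul_const", params = list(root = "q_m", mult = 1)),
    op_node("qm_compl", "sub_const", "qm_enc", list(const = 1),
            usage = "(beta_m - q_m)/2"),
    op_node("qm_exc", "mul_vars", c("qm_compl", "cc_half"),
            usage = "(beta_m - q_m)(C^a + C^v)/4"),
    op_node("g_s2a", "mul_const", params = list(root = "q_s2a", mult = 1),
            usage = "g(q_S2a)"),
    op_node("g_s2v", "mul_const", params = list(root = "q_s2v", mult = 1),
            usage = "g(q_S2v)"),
    op_node("s2_sum_half", "add_vars", c("g_s2v", "g_s2a"),
            list(weights = c(0.5, 0.5))),
    op_node("qm_inh_conv", "convolution", "s2_sum_half",
            list(kernel = "modulatory", scale = s_mod)),
    op_node("qm_inh_fac", "add_const", "qm_enc2",
            list(const = p$gamma_m / qm_inh_max,
                 mult = 2 * p$kappa_m / qm_inh_max),
            usage = "(gamma_m + kappa_m q_m)/(gamma_m + 2 kappa_m)"),
    op_node("qm_inh", "mul_vars", c("qm_inh_fac", "qm_inh_conv")),
    op_node("root_q_m", "ode_root", c("qm_exc", "qm_inh"),
            list(root = "q_m", tau = p$tau_d, alpha = p$alpha_d,
                 weights = c(2, -qm_inh_max * s_mod), state_scale = 2),
            usage = "dq_m/dt at half scale"),

    # cortical cross-inhibition circuit: auditory branch
    op_node("s1a_enc", "mul_const", params = list(root = "q_s1a", mult = 1)),
    op_node("s1a_compl", "sub_const", "s1a_enc", list(const = p$beta_d)),
    op_node("s1a_drive", "mul_vars", c("s1a_compl", "split_ca")),
    op_node("root_q_s1a", "ode_root", "s1a_drive",
            list(root = "q_s1a", tau = p$tau_d, alpha = p$alpha_d,
                 weights = 1, state_scale = 1)),
    op_node("g_s1a", "mul_const", params = list(root = "q_s1a", mult = 1),
            usage = "g(q_S1a)"),
    op_node("s2a_enc", "mul_const", params = list(root = "q_s2a", mult = 1)),
    op_node("s2a_compl", "sub_const", "s2a_enc", list(const = p$beta_d)),
    op_node("s2a_exc", "mul_vars", c("s2a_compl", "split_ca")),
    op_node("s2a_fac", "add_const", "s2a_enc",
            list(const = p$gamma_s2 / s2_inh_max, mult = 1 / s2_inh_max),
            usage = "(gamma_S2 + q_S2a)/(gamma_S2 + 1)"),
    op_node("s1v_conv", "convolution", "g_s1v",
            list(kernel = "lateral", scale = 1)),
    op_node("s2a_inh", "mul_vars", c("s2a_fac", "s1v_conv")),
    op_node("root_q_s2a", "ode_root", c("s2a_exc", "s2a_inh"),
            list(root = "q_s2a", tau = p$tau_d, alpha = p$alpha_d,
                 weights = c(1, -s2_inh_max), state_scale = 1)),

    # visual branch
    op_node("s1v_enc", "mul_const", params = list(root = "q_s1v", mult = 1)),
    op_node("s1v_compl", "sub_const", "s1v_enc", list(const = p$beta_d)),
    op_node("s1v_drive", "mul_vars", c("s1v_compl", "split_cv")),
    op_node("root_q_s1v", "ode_root", "s1v_drive",
            list(root = "q_s1v", tau = p$tau_d, alpha = p$alpha_d,
                 weights = 1, state_scale = 1)),
    op_node("g_s1v", "mul_const", params = list(root = "q_s1v", mult = 1),
            usage = "g(q_S1v)"),
    op_node("s2v_enc", "mul_const", params = list(root = "q_s2v", mult = 1)),
    op_node("s2v_compl", "sub_const", "s2v_enc", list(const = p$beta_d)),
    op_node("s2v_exc", "mul_vars", c("s2v_compl", "split_cv")),
    op_node("s2v_fac", "add_const", "s2v_enc",
            list(const = p$gamma_s2 / s2_inh_max, mult = 1 / s2_inh_max)),
    op_node("s1a_conv", "convolution", "g_s1a",
            list(kernel = "lateral", scale = 1)),
    op_node("s2v_inh", "mul_vars", c("s2v_fac", "s1a_conv")),
    op_node("root_q_s2v", "ode_root", c("s2v_exc", "s2v_inh"),
            list(root = "q_s2v", tau = p$tau_d, alpha = p$alpha_d,
                 weights = c(1, -s2_inh_max), state_scale = 1))
  )
  names(nodes) <- vapply(nodes, `[[`, character(1), "name")
  nodes <- topo_sort_nodes(nodes)
  structure(list(nodes = nodes, params = params), class = "msi_opgraph")
}

# Stable topological sort (state-reading nodes depend on roots only across
# steps, so only explicit `inputs` edges are ordered).
topo_sort_nodes <- function(nodes) {
  placed <- character(0)
  out <- list()
  remaining <- nodes
  while (length(remaining) > 0L) {
    ready <- vapply(remaining, function(nd) all(nd$inputs %in% placed),
                    logical(1))
    if (!any(ready)) stop("operation graph has a cycle", call. = FALSE)
    for (nd in remaining[ready]) out[[nd$name]] <- nd
    placed <- c(placed, names(remaining)[ready])
    remaining <- remaining[!ready]
  }
  out
}

#' @export
print.msi_opgraph <- function(x, ...) {
  kinds <- vapply(x$nodes, `[[`, character(1), "kind")
  cat("<msi_opgraph> ", length(x$nodes),
      " elementary operations per feature channel\n", sep = "")
  print(table(kinds))
  invisible(x)
}

#' Count operation nodes by kind
#'
#' @param graph An `msi_opgraph`.
#' @return Named integer vector of per-channel node counts per kind.
#' @export
op_counts <- function(graph) {
  stopifnot(inherits(graph, "msi_opgraph"))
  kinds <- vapply(graph$nodes, `[[`, character(1), "kind")
  table(factor(kinds, levels = c("input", "splitter", "add_const", "sub_const",
                                 "mul_const", "add_vars", "mul_vars",
                                 "convolution", "ode_root", "sigmoid")))
}

# --- graph interpreter -------------------------------------------------------

# Evaluate one node for one simulation step. `values` holds W x N binary
# matrices for already-evaluated nodes; `states` the real membrane vectors.
# Real-valued intermediate quantities (convolutions, weighted sums, shifted
# constants) are stochastically re-encoded as Bernoulli trains so that every
# edge of the graph carries a spike train in [0,1].
eval_node <- function(nd, values, states, kernels, W, n, rng, clipstat) {
  # `track` marks clipping as saturation to report; mul_const nodes realize
  # the rectified-linear transfer functions, whose clipping is intentional
  bern <- function(P, track = TRUE) {
    if (max(P) > 1) {
      if (track) clipstat$add(nd$name, mean(P > 1))
      P[P > 1] <- 1
    }
    if (min(P) < 0) P[P < 0] <- 0
    (rng(W * n) < P) * 1
  }
  row_broadcast <- function(v) matrix(v, W, n, byrow = TRUE)
  switch(nd$kind,
    input = bern(row_broadcast(nd$params$value)),
    splitter = values[[nd$inputs[1]]],
    mul_const = bern(row_broadcast(nd$params$mult * states[[nd$params$root]]),
                     track = FALSE),
    sigmoid = bern(row_broadcast(activation_h(states[[nd$params$root]],
                                              nd$params$slope))),
    sub_const = bern(nd$params$const - values[[nd$inputs[1]]]),
    add_const = bern(nd$params$const + nd$params$mult * values[[nd$inputs[1]]]),
    add_vars = {
      w <- nd$params$weights
      acc <- values[[nd$inputs[1]]] * w[1]
      for (j in seq_along(nd$inputs)[-1]) {
        acc <- acc + values[[nd$inputs[j]]] * w[j]
      }
      bern(acc)
    },
    convolution = bern((values[[nd$inputs[1]]] %*%
                          kernels[[nd$params$kernel]]) / nd$params$scale),
    mul_vars = {
      acc <- values[[nd$inputs[1]]]
      for (j in seq_along(nd$inputs)[-1]) acc <- acc * values[[nd$inputs[j]]]
      acc
    },
    ode_root = NULL, # handled by the stepper
    stop("unknown node kind: ", nd$kind, call. = FALSE)
  )
}

#' Simulate the spike-rate backend
#'
#' Runs the compiled operation graph: each Euler step of the dynamics is one
#' window of `ticks_per_step` ticks during which every graph edge carries a
#' Bernoulli spike train; products are computed by coincidence (AND),
#' convolutions and weighted sums on the per-tick spikes, and each root neuron
#' integrates the window-averaged drives into its membrane potential. Window
#' noise is strongly attenuated in the membrane because the leak time constant
#' averages over many hundreds of successive windows.
#'
#' @param inputs An `msi_inputs` object.
#' @param params An `msi_params` object.
#' @param ticks_per_step Window length per Euler step, default 1024.
#' @param seed Integer master seed; the run is bit-reproducible given the seed.
#' @param n_steps Optional override of `params$n_steps`.
#' @param graph Optional pre-compiled `msi_opgraph`.
#' @return An `msi_spike_result`: `states` (unscaled membrane potentials per
#'   population), `rates` (population activations: `h` for the SC output, `g`
#'   elsewhere), `sc_rate` (alias of the SC activation), and `saturation`
#'   (mean clipped fraction per node, only nodes that ever clipped).
#' @export
simulate_spiking <- function(inputs, params = msi_params(),
                             ticks_per_step = 1024L, seed = 1L,
                             n_steps = NULL, graph = NULL) {
  stopifnot(inherits(inputs, "msi_inputs"))
  validate_msi_params(params)
  if (is.null(graph)) graph <- compile_model(params)
  W <- as.integer(ticks_per_step)
  if (W < 1L) stop("'ticks_per_step' must be >= 1", call. = FALSE)
  n <- params$n_neurons
  steps <- if (is.null(n_steps)) params$n_steps else as.integer(n_steps)
  kernels <- model_kernels(params)
  kernels <- lapply(kernels, unclass)
  # own RNG scope: seed the stream once, restore the caller's state on exit
  genv <- globalenv()
  had_seed <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had_seed) {
    old_seed <- get(".Random.seed", envir = genv)
    on.exit(assign(".Random.seed", old_seed, envir = genv), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv), add = TRUE)
  }
  set.seed(child_seed(seed, 40L))
  rng <- stats::runif

  clip_env <- new.env()
  clip_env$tab <- list()
  clipstat <- list(add = function(name, frac) {
    clip_env$tab[[name]] <- c(clip_env$tab[[name]], frac)
  })

  nodes <- graph$nodes
  roots <- Filter(function(nd) nd$kind == "ode_root", nodes)
  states <- stats::setNames(rep(list(numeric(n)), length(STATE_FIELDS)),
                            STATE_FIELDS)
  # bind the external fields into the input nodes once
  for (nm in names(nodes)) {
    if (nodes[[nm]]$kind == "input") {
      nodes[[nm]]$params$value <- inputs[[nodes[[nm]]$params$field]]
    }
  }
  dt <- params$dt
  for (step in seq_len(steps)) {
    values <- list()
    for (nd in nodes) {
      if (nd$kind == "ode_root") next
      values[[nd$name]] <- eval_node(nd, values, states, kernels, W, n, rng,
                                     clipstat)
    }
    for (nd in roots) {
      pr <- nd$params
      drive <- numeric(n)
      w <- pr$weights
      for (j in seq_along(nd$inputs)) {
        drive <- drive + w[j] * colMeans(values[[nd$inputs[j]]])
      }
      states[[pr$root]] <- states[[pr$root]] +
        (dt / pr$tau) * (-pr$alpha * states[[pr$root]] + drive)
    }
  }
  scales <- stats::setNames(rep(1, length(STATE_FIELDS)), STATE_FIELDS)
  for (nd in roots) scales[nd$params$root] <- nd$params$state_scale
  unscaled <- stats::setNames(
    lapply(STATE_FIELDS, function(f) states[[f]] * scales[f]), STATE_FIELDS)
  rates <- list(
    r = activation_h(unscaled$r, params$slope_h),
    p_sen = activation_g(unscaled$p_sen, params$slope_g_sen),
    p_pool = activation_g(unscaled$p_pool),
    q_m = activation_g(unscaled$q_m),
    q_s1a = activation_g(unscaled$q_s1a),
    q_s2a = activation_g(unscaled$q_s2a),
    q_s1v = activation_g(unscaled$q_s1v),
    q_s2v = activation_g(unscaled$q_s2v)
  )
  sat <- vapply(clip_env$tab, function(v) sum(v) / steps, numeric(1))
  heavy <- sat[sat > 0.01]
  if (length(heavy) > 0L) {
    warning("clipping engaged on > 1% of ticks in node(s): ",
            paste(names(heavy), collapse = ", "), call. = FALSE)
  }
  structure(list(states = unscaled, rates = rates, sc_rate = rates$r,
                 saturation = sat, ticks_per_step = W, n_steps = steps),
            class = "msi_spike_result")
}

#' @export
print.msi_spike_result <- function(x, ...) {
  cat("<msi_spike_result> ", x$n_steps, " steps x ", x$ticks_per_step,
      " ticks; peak SC rate ", signif(max(x$sc_rate), 4), "\n", sep = "")
  invisible(x)
}

#' Compare spike-backend and rate-model equilibria
#'
#' Runs both backends on the same inputs and tabulates, per population and
#' channel, the equilibrium activation of the rate model against the
#' spike-rate emulation.
#'
#' @inheritParams simulate_spiking
#' @return Data frame with columns `population`, `channel`,
#'   `rate_model_value`, `spike_value`, `abs_error`.
#' @export
spike_compare <- function(inputs, params = msi_params(),
                          ticks_per_step = 1024L, seed = 1L, n_steps = NULL) {
  p <- params
  if (!is.null(n_steps)) p$n_steps <- as.integer(n_steps)
  rate_res <- simulate(inputs, p)
  spike_res <- simulate_spiking(inputs, params, ticks_per_step, seed,
                                n_steps = n_steps)
  fs <- rate_res$final_state
  rate_acts <- list(
    r = activation_h(fs$r, p$slope_h),
    p_sen = activation_g(fs$p_sen, p$slope_g_sen),
    p_pool = activation_g(fs$p_pool),
    q_m = activation_g(fs$q_m),
    q_s1a = activation_g(fs$q_s1a),
    q_s2a = activation_g(fs$q_s2a),
    q_s1v = activation_g(fs$q_s1v),
    q_s2v = activation_g(fs$q_s2v)
  )
  rows <- lapply(STATE_FIELDS, function(f) {
    data.frame(population = f,
               channel = seq_along(rate_acts[[f]]) - 1L,
               rate_model_value = rate_acts[[f]],
               spike_value = spike_res$rates[[f]],
               abs_error = abs(rate_acts[[f]] - spike_res$rates[[f]]))
  })
  do.call(rbind, rows)
}
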