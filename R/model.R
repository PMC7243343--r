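#' Input field set for one stimulus presentation
#'
#' Bundles the four nonnegative activity fields that drive the network: the
#' sensory auditory and visual inputs (ascending, from ICx and superficial SC)
#' and the cortical auditory and visual signals (descending, from the AEv/FAEs
#' association areas). All four are length-N vectors over azimuthal channels.
#'
#' @param s_a,s_v Sensory auditory / visual fields (nonnegative, length N).
#' @param c_a,c_v Cortical auditory / visual fields (nonnegative, length N).
#' @return An object of class `msi_inputs`.
#' @export
msi_inputs <- function(s_a, s_v, c_a, c_v) {
  fields <- list(s_a = s_a, s_v = s_v, c_a = c_a, c_v = c_v)
  n <- length(s_a)
  for (f in names(fields)) {
    v <- fields[[f]]
    if (!is.numeric(v) || length(v) != n) {
      stop("input field '", f, "' must be numeric of length ", n, call. = FALSE)
    }
    if (any(!is.finite(v)) || any(v < 0)) {
      stop("input field '", f, "' must be finite and nonnegative", call. = FALSE)
    }
  }
  structure(fields, n = n, class = "msi_inputs")
}

#' @export
print.msi_inputs <- function(x, ...) {
  cat("<msi_inputs> ", attr(x, "n"), " channels; peak s_a = ",
      signif(max(x$s_a), 4), ", s_v = ", signif(max(x$s_v), 4),
      ", c_a = ", signif(max(x$c_a), 4), ", c_v = ", signif(max(x$c_v), 4),
      "\n", sep = "")
  invisible(x)
}

# Population names in the order they appear in the state equations.
STATE_FIELDS <- c("r", "p_sen", "p_pool", "q_m", "q_s1a", "q_s2a", "q_s1v", "q_s2v")

#' Zero network state
#'
#' All eight membrane-potential vectors (SC output `r`, coincidence detector
#' `p_sen`, normalization pool `p_pool`, modulatory interneuron `q_m` and the
#' four cortical cross-inhibition populations `q_s1a`, `q_s2a`, `q_s1v`,
#' `q_s2v`) initialized to zero, the model's resting condition at stimulus
#' onset.
#'
#' @param n Number of channels.
#' @return Named list of eight zero vectors, class `msi_state`.
#' @export
msi_state0 <- function(n) {
  s <- stats::setNames(rep(list(numeric(n)), length(STATE_FIELDS)), STATE_FIELDS)
  class(s) <- "msi_state"
  s
}

# Internal: coerce state/input fields to n x b matrices for batched stepping.
as_batch <- function(x, n) {
  if (is.matrix(x)) x else matrix(x, nrow = n)
}

#' Drive terms of the SC membrane equation
#'
#' Computes the three aggregated input terms of the SC neurons for the current
#' state: the excitatory drive `EX = S^a + S^v` (pointwise, deliberately
#' without a spatial kernel), the modulatory cortical drive
#' `MOD_i = sum_j K^m_ij g(q_m_j)` and the inhibitory drive
#' `INH_i = sum_j K_ij g(p_pool_j) + sum_j K_ij g_sen(p_sen_j)` where `g_sen`
#' is the rectifier with slope `slope_g_sen`.
#'
#' @param state An `msi_state` (or batched equivalent with matrix fields).
#' @param inputs An `msi_inputs` object (or batched fields).
#' @param params An `msi_params` object.
#' @param kernels Optional list with elements `lateral` and `modulatory`
#'   as returned by the internal kernel builder; recomputed if missing.
#' @return List with numeric components `EX`, `MOD`, `INH`, same shape as the
#'   state fields.
#' @export
compute_drives <- function(state, inputs, params, kernels = NULL) {
  if (is.null(kernels)) kernels <- model_kernels(params)
  n <- params$n_neurons
  dim_of <- function(x) if (is.matrix(x)) nrow(x) else length(x)
  if (dim_of(inputs$s_a) != n || dim_of(inputs$s_v) != n) {
    stop("input length does not match n_neurons", call. = FALSE)
  }
  if (dim_of(state$q_m) != n || dim_of(state$p_pool) != n ||
      dim_of(state$p_sen) != n) {
    stop("state length does not match n_neurons", call. = FALSE)
  }
  sa <- as_batch(inputs$s_a, n); sv <- as_batch(inputs$s_v, n)
  qm <- as_batch(state$q_m, n)
  ppool <- as_batch(state$p_pool, n)
  psen <- as_batch(state$p_sen, n)
  EX <- sa + sv
  MOD <- kernels$modulatory %*% activation_g(qm)
  INH <- kernels$lateral %*% activation_g(ppool) +
    kernels$lateral %*% activation_g(psen, k = params$slope_g_sen)
  drop_like <- function(m, template) if (is.matrix(template)) m else drop(m)
  list(EX = drop_like(EX, inputs$s_a),
       MOD = drop_like(MOD, state$q_m),
       INH = drop_like(INH, state$q_m))
}

# One synchronous forward-Euler update of all eight populations, batched:
# every state/input field is an n x b matrix. Returns the updated state list.
euler_step_batch <- function(state, inputs, params, kernels) {
  K <- kernels$lateral
  Km <- kernels$modulatory
  p <- params

  r <- state$r; p_sen <- state$p_sen; p_pool <- state$p_pool; q_m <- state$q_m
  q_s1a <- state$q_s1a; q_s2a <- state$q_s2a
  q_s1v <- state$q_s1v; q_s2v <- state$q_s2v
  sa <- inputs$s_a; sv <- inputs$s_v; ca <- inputs$c_a; cv <- inputs$c_v

  EX <- sa + sv
  MOD <- Km %*% activation_g(q_m)
  INH <- K %*% activation_g(p_pool) +
    K %*% activation_g(p_sen, k = p$slope_g_sen)

  new <- list(
    r = r + (p$dt / p$tau_d) *
      (-p$alpha_d * r + (p$beta_d - r) * EX * (1 + p$lam * MOD) -
         p$kappa_r * r * INH),
    p_sen = p_sen + (p$dt / p$tau_sen) *
      (-p$alpha_sen * p_sen + (p$beta_d - p_sen) * (sa * sv)),
    p_pool = p_pool + (p$dt / p$tau_d) *
      (-p$alpha_d * p_pool +
         (p$beta_d - p_pool) * (K %*% activation_h(r, p$slope_h))),
    q_m = q_m + (p$dt / p$tau_d) *
      (-p$alpha_d * q_m + (p$beta_m - q_m) * (ca + cv) -
         (p$gamma_m + p$kappa_m * q_m) *
           (Km %*% (activation_g(q_s2v) + activation_g(q_s2a)))),
    q_s1a = q_s1a + (p$dt / p$tau_d) *
      (-p$alpha_d * q_s1a + (p$beta_d - q_s1a) * ca),
    q_s2a = q_s2a + (p$dt / p$tau_d) *
      (-p$alpha_d * q_s2a + (p$beta_d - q_s2a) * ca -
         (p$gamma_s2 + q_s2a) * (K %*% activation_g(q_s1v))),
    q_s1v = q_s1v + (p$dt / p$tau_d) *
      (-p$alpha_d * q_s1v + (p$beta_d - q_s1v) * cv),
    q_s2v = q_s2v + (p$dt / p$tau_d) *
      (-p$alpha_d * q_s2v + (p$beta_d - q_s2v) * cv -
         (p$gamma_s2 + q_s2v) * (K %*% activation_g(q_s1a)))
  )
  for (f in STATE_FIELDS) {
    if (any(!is.finite(new[[f]]))) {
      stop("numeric instability: non-finite value in population '", f, "'",
           call. = FALSE)
    }
  }
  new
}

#' One forward-Euler step of the full network
#'
#' Advances all eight membrane-potential equations by one step `dt`,
#' synchronously: every population is updated from the same pre-step snapshot,
#' so the result does not depend on any update ordering.
#'
#' @inheritParams compute_drives
#' @return Updated `msi_state`.
#' @export
euler_step <- function(state, inputs, params, kernels = NULL) {
  if (is.null(kernels)) kernels <- model_kernels(params)
  n <- params$n_neurons
  sm <- lapply(state[STATE_FIELDS], as_batch, n = n)
  im <- lapply(unclass(inputs)[c("s_a", "s_v", "c_a", "c_v")], as_batch, n = n)
  out <- euler_step_batch(sm, im, params, kernels)
  if (!is.matrix(state$r)) out <- lapply(out, drop)
  class(out) <- "msi_state"
  out
}

# Batched integration: `inputs` fields are n x b matrices. Returns final state
# (matrices), sc_rate matrix and per-run residual (max abs one-step change).
simulate_batch_core <- function(input_mats, params, kernels,
                                trajectory_stride = 0L) {
  n <- params$n_neurons
  b <- ncol(input_mats$s_a)
  state <- stats::setNames(
    rep(list(matrix(0, n, b)), length(STATE_FIELDS)), STATE_FIELDS)
  traj <- if (trajectory_stride > 0L) list() else NULL
  prev_r <- NULL
  residual <- rep(NA_real_, b)
  for (step in seq_len(params$n_steps)) {
    prev <- state
    state <- euler_step_batch(state, input_mats, params, kernels)
    if (any(vapply(state, function(m) max(abs(m)), numeric(1)) > 1e6)) {
      stop("numeric instability: membrane potential exceeded 1e6", call. = FALSE)
    }
    if (!is.null(traj) && (step %% trajectory_stride == 0L)) {
      traj[[length(traj) + 1L]] <- state
    }
    if (step == params$n_steps) {
      delta <- mapply(function(a, z) abs(a - z), state, prev, SIMPLIFY = FALSE)
      dmax <- Reduce(pmax, delta)
      residual <- apply(dmax, 2, max)
    }
  }
  list(final_state = state,
       sc_rate = activation_h(state$r, params$slope_h),
       residual = residual,
       trajectory = traj)
}

#' Integrate the network to equilibrium for one stimulus
#'
#' Runs `n_steps` forward-Euler steps from the zero resting state with the
#' stimulus fields held constant, the standard presentation protocol for this
#' model. Returns the final state, the SC firing-rate profile `h(r)` and the
#' numerical residual (maximum absolute single-step state change at the last
#' step), which quantifies how close the run is to its fixed point.
#'
#' @param inputs An `msi_inputs` object.
#' @param params An `msi_params` object.
#' @param trajectory_stride If > 0, additionally record the state every this
#'   many steps (a list of `msi_state` snapshots).
#' @return An object of class `msi_result` with components `final_state`
#'   (`msi_state`), `sc_rate` (length-N rates in `[0, 1)`), `residual`
#'   (scalar) and `trajectory` (list or `NULL`).
#' @export
#' @examples
#' p <- msi_params(n_steps = 500)
#' stim <- build_condition_inputs(condition_spec("bimodal_full", intensity = 0.4), p$n_neurons)
#' res <- simulate(stim, p)
#' which.max(res$sc_rate) - 1 # peak location
simulate <- function(inputs, params = msi_params(), trajectory_stride = 0L) {
  stopifnot(inherits(inputs, "msi_inputs"))
  validate_msi_params(params)
  if (attr(inputs, "n") != params$n_neurons) {
    stop("inputs have ", attr(inputs, "n"), " channels but params$n_neurons = ",
         params$n_neurons, call. = FALSE)
  }
  kernels <- model_kernels(params)
  input_mats <- lapply(unclass(inputs)[c("s_a", "s_v", "c_a", "c_v")],
                       matrix, nrow = params$n_neurons)
  out <- simulate_batch_core(input_mats, params, kernels,
                             trajectory_stride = as.integer(trajectory_stride))
  final <- lapply(out$final_state, drop)
  class(final) <- "msi_state"
  structure(list(final_state = final,
                 sc_rate = drop(out$sc_rate),
                 residual = out$residual[1L],
                 trajectory = out$trajectory),
            class = "msi_result")
}

#' @export
print.msi_result <- function(x, ...) {
  cat("<msi_result> peak SC rate ", signif(max(x$sc_rate), 4),
      " at location ", which.max(x$sc_rate) - 1L,
      "; residual ", format(x$residual, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Integrate many stimulus presentations in one batched run
#'
#' Equivalent to calling [simulate()] on each element of `inputs_list` but
#' executed as a single matrix-valued Euler integration (all runs share the
#' parameter set), which is much faster for the sweep experiments.
#'
#' @param inputs_list List of `msi_inputs`, all with `params$n_neurons` channels.
#' @param params An `msi_params` object.
#' @return List with `sc_rate` (N x B matrix of firing rates `h(r)`, one
#'   column per run), `membrane` (N x B matrix of SC membrane potentials, the
#'   readout used by the response metrics) and `residual` (length-B vector).
#' @export
simulate_batch <- function(inputs_list, params = msi_params()) {
  stopifnot(length(inputs_list) >= 1L)
  validate_msi_params(params)
  n <- params$n_neurons
  for (inp in inputs_list) {
    if (attr(inp, "n") != n) stop("all inputs must have n_neurons channels", call. = FALSE)
  }
  grab <- function(f) vapply(inputs_list, function(inp) inp[[f]], numeric(n))
  input_mats <- list(s_a = grab("s_a"), s_v = grab("s_v"),
                     c_a = grab("c_a"), c_v = grab("c_v"))
  input_mats <- lapply(input_mats, matrix, nrow = n) # keep matrix when B = 1
  kernels <- model_kernels(params)
  out <- simulate_batch_core(input_mats, params, kernels)
  list(sc_rate = out$sc_rate, membrane = out$final_state$r,
       residual = out$residual)
}
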