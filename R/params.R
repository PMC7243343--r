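#' Model parameters for the multisensory integration network
#'
#' Constructs the full parameter set of the rate-based superior colliculus (SC)
#' model: membrane constants shared by all populations, the SC neuron's divisive
#' inhibition and modulatory gain, the constants of the cortical cross-modal
#' inhibition circuit, kernel widths and the Euler integration settings.
#' Defaults reproduce the published operating point of the model.
#'
#' @param n_neurons Number of neurons per population (spatial channels covering
#'   azimuthal locations `0 .. n_neurons - 1`). Default 20.
#' @param tau_d Membrane time constant of all populations except the coincidence
#'   detector. Default 1.0.
#' @param alpha_d Passive leak rate. Default 1.0.
#' @param beta_d Saturation level of excitatory input. Default 1.0.
#' @param kappa_r Strength of divisive inhibition onto SC neurons. Default 0.25.
#' @param lam Gain of the modulatory cortical feedback (lambda). Default 0.4.
#'   Setting `lam = 0` removes the multiplicative effect of feedback while
#'   leaving the circuit in place.
#' @param sigma_mod Width of the Gaussian kernel of the modulatory projection
#'   (sigma^m). Default 3.0.
#' @param sigma_kernel Width of all other Gaussian interaction kernels.
#'   Default 1.0.
#' @param kappa_m,gamma_m,beta_m Constants of the modulatory interneuron:
#'   shunting coefficient, subtractive inhibition strength and excitatory
#'   saturation. Defaults 1.0, 5.0, 2.0.
#' @param kappa_s2,gamma_s2 Constants of the S2 cortical neurons. `kappa_s2`
#'   is carried for completeness but the S2 state equations use an implicit
#'   shunting coefficient of 1. Defaults 1.0, 5.0.
#' @param tau_sen,alpha_sen Time constant and leak of the feedforward
#'   coincidence-detector population; default to the shared membrane constants
#'   (1.0, 1.0).
#' @param slope_h Slope constant of the sigmoidal SC activation. Default 3.4.
#' @param slope_g_sen Slope of the rectified-linear activation applied to the
#'   coincidence detector's output. Default 2.0.
#' @param l_unused Constant `l = 3.6` listed with the SC neuron parameters but
#'   not referenced by any state equation; stored verbatim and never used.
#' @param dt Forward-Euler step size. Default 0.001.
#' @param n_steps Number of Euler steps per stimulus presentation. Default 4000.
#'
#' @return An object of class `msi_params` (a named list).
#' @export
#' @examples
#' p <- msi_params()
#' p$lam
#' p_fast <- msi_params(n_steps = 1000)
msi_params <- function(n_neurons = 20L,
                       tau_d = 1.0, alpha_d = 1.0, beta_d = 1.0,
                       kappa_r = 0.25, lam = 0.4,
                       sigma_mod = 3.0, sigma_kernel = 1.0,
                       kappa_m = 1.0, gamma_m = 5.0, beta_m = 2.0,
                       kappa_s2 = 1.0, gamma_s2 = 5.0,
                       tau_sen = 1.0, alpha_sen = 1.0,
                       slope_h = 3.4, slope_g_sen = 2.0,
                       l_unused = 3.6,
                       dt = 0.001, n_steps = 4000L) {
  p <- list(
    n_neurons = as.integer(n_neurons),
    tau_d = tau_d, alpha_d = alpha_d, beta_d = beta_d,
    kappa_r = kappa_r, lam = lam,
    sigma_mod = sigma_mod, sigma_kernel = sigma_kernel,
    kappa_m = kappa_m, gamma_m = gamma_m, beta_m = beta_m,
    kappa_s2 = kappa_s2, gamma_s2 = gamma_s2,
    tau_sen = tau_sen, alpha_sen = alpha_sen,
    slope_h = slope_h, slope_g_sen = slope_g_sen,
    l_unused = l_unused,
    dt = dt, n_steps = as.integer(n_steps)
  )
  class(p) <- "msi_params"
  validate_msi_params(p)
  p
}

validate_msi_params <- function(p) {
  stopifnot(is.list(p))
  num_fields <- setdiff(names(p), c("n_neurons", "n_steps"))
  for (f in num_fields) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || !is.finite(p[[f]])) {
      stop("parameter '", f, "' must be a single finite number", call. = FALSE)
    }
  }
  pos <- c("tau_d", "alpha_d", "beta_d", "sigma_mod", "sigma_kernel",
           "tau_sen", "alpha_sen", "slope_h", "slope_g_sen", "dt")
  for (f in pos) {
    if (p[[f]] <= 0) stop("parameter '", f, "' must be strictly positive", call. = FALSE)
  }
  if (p$lam < 0) stop("parameter 'lam' must be >= 0", call. = FALSE)
  if (p$n_neurons < 2L) stop("'n_neurons' must be >= 2", call. = FALSE)
  if (p$n_steps < 1L) stop("'n_steps' must be >= 1", call. = FALSE)
  invisible(p)
}

#' @export
print.msi_params <- function(x, ...) {
  cat("<msi_params> ", x$n_neurons, " neurons/population, dt = ", x$dt,
      ", n_steps = ", x$n_steps, "\n", sep = "")
  cat("  SC: kappa_r = ", x$kappa_r, ", lambda = ", x$lam,
      ", slope_h = ", x$slope_h, "\n", sep = "")
  cat("  modulatory: beta_m = ", x$beta_m, ", gamma_m = ", x$gamma_m,
      ", kappa_m = ", x$kappa_m, ", sigma_m = ", x$sigma_mod, "\n", sep = "")
  cat("  S2: gamma_s2 = ", x$gamma_s2, " (kappa_s2 = ", x$kappa_s2,
      ", implicit 1 in the dynamics; l = ", x$l_unused, " stored, unused)\n",
      sep = "")
  invisible(x)
}

#' Load model parameters from a YAML or JSON config file
#'
#' Reads a flat key-value file of parameter overrides and merges it with the
#' built-in defaults. Keys must be valid [msi_params()] argument names; unknown
#' keys are rejected so that typos cannot silently fall back to defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `msi_params` object.
#' @export
load_params <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- read_config_file(path)
  params_from_list(cfg)
}

#' @rdname load_params
#' @param overrides Named list of parameter overrides (possibly empty).
#' @export
params_from_list <- function(overrides) {
  overrides <- as.list(overrides)
  legal <- names(formals(msi_params))
  bad <- setdiff(names(overrides), legal)
  if (length(bad) > 0L) {
    stop("unknown parameter key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(msi_params, overrides)
}

read_config_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config file must be .yaml, .yml or .json: ", path, call. = FALSE)
  }
}

#' Gaussian interaction kernel between neuron populations
#'
#' Builds the full `n` x `n` matrix of Gaussian interaction weights
#' `K[i, j] = 1/(sigma * sqrt(2*pi)) * exp(-0.5 * ((i - j)/sigma)^2)`.
#' The kernel is evaluated on the finite azimuthal array without wraparound or
#' truncation: channels near the border simply receive less total lateral input
#' (zero padding).
#'
#' @param sigma Kernel width in channels (> 0).
#' @param n Number of channels (>= 2).
#' @param normalize If `TRUE` (default) the kernel carries the Gaussian
#'   normalization `1/(sigma * sqrt(2*pi))` so its rows integrate to ~1; with
#'   `FALSE` the peak weight is 1 regardless of width. The lateral
#'   (normalization and coincidence) interactions use the normalized form;
#'   the cortical feedback path uses the unit-amplitude form so that the
#'   strength of modulation and of the cross-modal veto does not shrink with
#'   their spatial spread.
#' @return An `msi_kernel` object: the weight matrix with a `sigma` attribute.
#' @export
#' @examples
#' K <- make_kernel(sigma = 1, n = 20)
#' K[1, 1] # 1/sqrt(2*pi)
make_kernel <- function(sigma, n, normalize = TRUE) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0) {
    stop("'sigma' must be a single positive number", call. = FALSE)
  }
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("'n' must be an integer >= 2", call. = FALSE)
  idx <- seq_len(n) - 1L
  d <- outer(idx, idx, "-")
  w <- exp(-0.5 * (d / sigma)^2)
  if (normalize) w <- w / (sigma * sqrt(2 * pi))
  structure(w, sigma = sigma, class = c("msi_kernel", class(w)))
}

# Kernels used by the dynamics. Lateral interactions (pool normalization,
# coincidence inhibition, S1 -> S2 veto) are narrow and normalized; the
# cortical feedback path (q_m -> SC modulation and the S2 -> q_m cross-modal
# veto) is broad (sigma^m) at unit peak amplitude.
model_kernels <- function(params) {
  list(
    lateral = make_kernel(params$sigma_kernel, params$n_neurons),
    modulatory = make_kernel(params$sigma_mod, params$n_neurons,
                             normalize = FALSE)
  )
}
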