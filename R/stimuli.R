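#' Gaussian stimulus specification
#'
#' A single stimulus is a Gaussian activity bump over the azimuthal channel
#' array, parameterized by its center location `x_t` (real-valued, in channel
#' units), its width `sigma` (the cue's spatial uncertainty) and its peak
#' `intensity`.
#'
#' @param center Real location in `[0, n - 1]` channel coordinates.
#' @param sigma Gaussian width (> 0), default 1.
#' @param intensity Peak intensity (>= 0), default 1.
#' @return An object of class `msi_stimulus`.
#' @export
stimulus_spec <- function(center, sigma = 1, intensity = 1) {
  if (!is.numeric(sigma) || sigma <= 0) stop("'sigma' must be > 0", call. = FALSE)
  if (!is.numeric(intensity) || !is.finite(intensity) || intensity < 0) {
    stop("'intensity' must be finite and >= 0", call. = FALSE)
  }
  structure(list(center = center, sigma = sigma, intensity = intensity),
            class = "msi_stimulus")
}

#' Evaluate a Gaussian stimulus on the channel array
#'
#' `y_i = intensity * exp(-(i - center)^2 / (2 * sigma^2))` for integer
#' channels `i = 0 .. n-1`. Centers may be real-valued; the field is sampled
#' at the channel grid without snapping the center.
#'
#' @param spec An `msi_stimulus` (see [stimulus_spec()]).
#' @param n Number of channels.
#' @return Nonnegative numeric vector of length `n`.
#' @export
#' @examples
#' gaussian_input(stimulus_spec(center = 8, intensity = 0.7), 20)[9] # 0.7
gaussian_input <- function(spec, n) {
  stopifnot(inherits(spec, "msi_stimulus"))
  i <- seq_len(n) - 1L
  exp(-(i - spec$center)^2 / (2 * spec$sigma^2)) * spec$intensity
}

# The six stimulus conditions of the sweep experiments.
MSI_CONDITIONS <- c("bimodal_no_cortex", "bimodal_full",
                    "bimodal_ctx_audio_only", "bimodal_ctx_visual_only",
                    "unimodal_visual", "unimodal_audio")

#' Stimulus condition specification
#'
#' Pairs an auditory and a visual stimulus with one of the six canonical
#' conditions: bimodal with no cortical feedback, bimodal with full feedback,
#' bimodal with only one cortical modality active (two conditions), and the
#' two unimodal controls (sensory plus matching cortical input of a single
#' modality).
#'
#' @param condition One of `"bimodal_no_cortex"`, `"bimodal_full"`,
#'   `"bimodal_ctx_audio_only"`, `"bimodal_ctx_visual_only"`,
#'   `"unimodal_visual"`, `"unimodal_audio"`.
#' @param audio,visual `msi_stimulus` specs. Defaults: both centered at
#'   location 8 with `sigma = 1` and the shared `intensity`.
#' @param intensity Convenience intensity used for both default specs.
#' @return An object of class `msi_condition`.
#' @export
condition_spec <- function(condition,
                           audio = stimulus_spec(8, 1, intensity),
                           visual = stimulus_spec(8, 1, intensity),
                           intensity = 1) {
  condition <- match.arg(condition, MSI_CONDITIONS)
  stopifnot(inherits(audio, "msi_stimulus"), inherits(visual, "msi_stimulus"))
  structure(list(condition = condition, audio = audio, visual = visual),
            class = "msi_condition")
}

#' Build the input fields for a stimulus condition
#'
#' Sensory fields are Gaussian bumps per the condition; when a cortical
#' pathway is active its field copies the corresponding sensory spec exactly
#' (same center, width and intensity), reflecting that the descending cortical
#' signals share the activity characteristics of their sensory counterparts.
#' Unimodal conditions zero both the sensory and the cortical field of the
#' other modality. Use `cortical_audio`/`cortical_visual` to override the
#' cortical specs (e.g. to pin the cortical focus at a fixed location while
#' the sensory stimulus moves).
#'
#' @param cond An `msi_condition`.
#' @param n Number of channels.
#' @param cortical_audio,cortical_visual Optional `msi_stimulus` overrides for
#'   the cortical fields (applied only where the condition activates them).
#' @return An `msi_inputs` object.
#' @export
build_condition_inputs <- function(cond, n,
                                   cortical_audio = NULL,
                                   cortical_visual = NULL) {
  stopifnot(inherits(cond, "msi_condition"))
  zero <- numeric(n)
  sa <- gaussian_input(cond$audio, n)
  sv <- gaussian_input(cond$visual, n)
  ca_spec <- if (is.null(cortical_audio)) cond$audio else cortical_audio
  cv_spec <- if (is.null(cortical_visual)) cond$visual else cortical_visual
  ca <- gaussian_input(ca_spec, n)
  cv <- gaussian_input(cv_spec, n)
  f <- switch(cond$condition,
    bimodal_no_cortex = list(sa, sv, zero, zero),
    bimodal_full = list(sa, sv, ca, cv),
    bimodal_ctx_audio_only = list(sa, sv, ca, zero),
    bimodal_ctx_visual_only = list(sa, sv, zero, cv),
    unimodal_visual = list(zero, sv, zero, cv),
    unimodal_audio = list(sa, zero, ca, zero)
  )
  msi_inputs(s_a = f[[1]], s_v = f[[2]], c_a = f[[3]], c_v = f[[4]])
}

#' Inputs for the within-modality (two auditory stimuli) experiment
#'
#' The second auditory stimulus (input B) is delivered through the visual
#' sensory channel `s_v` while the visual cortical field stays zero: only the
#' auditory cortical projection (following input A) is active, so the
#' cross-modal feedback circuit never opens and any interaction between A and
#' B is purely within-modality.
#'
#' @param audio_a,audio_b `msi_stimulus` specs for the two auditory stimuli.
#' @param n Number of channels.
#' @return An `msi_inputs` object with `c_v = 0`.
#' @export
build_within_modality_inputs <- function(audio_a, audio_b, n) {
  stopifnot(inherits(audio_a, "msi_stimulus"), inherits(audio_b, "msi_stimulus"))
  msi_inputs(s_a = gaussian_input(audio_a, n),
             s_v = gaussian_input(audio_b, n),
             c_a = gaussian_input(audio_a, n),
             c_v = numeric(n))
}

#' Synthetic sensor-like input fixture
#'
#' Generates a 19-channel input set that mimics the statistics of neuromorphic
#' sensor recordings (an event camera downsampled to 19 azimuthal channels and
#' an interaural-level-difference localizer): clean Gaussian bumps corrupted by
#' seeded multiplicative jitter plus a low-amplitude background floor, clipped
#' to `[0, 1]`. This is a synthetic stand-in for real recordings, intended for
#' stress-testing the model on non-ideal inputs; it carries no measured data.
#'
#' @param audio_center,visual_center Bump locations in channel coordinates.
#' @param noise_level Jitter scale (>= 0); 0 yields pure Gaussian bumps.
#' @param seed Integer seed; the fixture is deterministic given the seed.
#' @param intensity Peak intensity of both bumps, default 0.7.
#' @param sigma Bump width, default 1.
#' @param n Number of channels, default 19.
#' @param cortical If `TRUE` (default) cortical fields copy the clean bumps
#'   (the cortical estimate is assumed noise-free); if `FALSE` they are zero.
#' @return An `msi_inputs` object on `n` channels.
#' @export
sensor_like_fixture <- function(audio_center, visual_center, noise_level, seed,
                                intensity = 0.7, sigma = 1, n = 19L,
                                cortical = TRUE) {
  if (noise_level < 0) stop("'noise_level' must be >= 0", call. = FALSE)
  a_clean <- gaussian_input(stimulus_spec(audio_center, sigma, intensity), n)
  v_clean <- gaussian_input(stimulus_spec(visual_center, sigma, intensity), n)
  noisy <- function(clean, stream) {
    rng <- rng_stream(seed, stream)
    jitter <- 1 + noise_level * (rng(n) * 2 - 1)
    background <- 0.05 * noise_level * rng(n)
    pmin(pmax(clean * jitter + background, 0), 1)
  }
  sa <- noisy(a_clean, 1L)
  sv <- noisy(v_clean, 2L)
  if (cortical) {
    msi_inputs(sa, sv, pmin(a_clean, 1), pmin(v_clean, 1))
  } else {
    msi_inputs(sa, sv, numeric(n), numeric(n))
  }
}
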