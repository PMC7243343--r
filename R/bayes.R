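#' Stimulus-location distribution specification for the fusion experiment
#'
#' Each modality's stimulus location is drawn from a normal distribution; the
#' drawn location also sets the center of that modality's Gaussian input field
#' and the distribution's sigma sets the field's width, so the network sees
#' the cue's spatial uncertainty directly.
#'
#' @param mu_a,mu_v Means of the auditory / visual location distributions
#'   (channel coordinates).
#' @param sigma_a,sigma_v Standard deviations (> 0).
#' @param n_draws Number of independent stimulus draws, default 200.
#' @param seed Integer seed for the draws.
#' @return An object of class `msi_fusion_spec`.
#' @export
fusion_spec <- function(mu_a, mu_v, sigma_a, sigma_v,
                        n_draws = 200L, seed = 1L) {
  if (sigma_a <= 0 || sigma_v <= 0) stop("sigmas must be > 0", call. = FALSE)
  if (n_draws < 1L) stop("'n_draws' must be >= 1", call. = FALSE)
  structure(list(mu_a = mu_a, mu_v = mu_v,
                 sigma_a = sigma_a, sigma_v = sigma_v,
                 n_draws = as.integer(n_draws), seed = as.integer(seed)),
            class = "msi_fusion_spec")
}

#' Analytic reliability-weighted posterior of two location cues
#'
#' The optimal fusion of two Gaussian location cues weights each cue by its
#' inverse variance: `w_a = (1/sigma_a^2) / (1/sigma_a^2 + 1/sigma_v^2)`
#' (and symmetrically `w_v`), giving fused mean
#' `mu_cp = mu_a * w_a + mu_v * w_v` and fused standard deviation
#' `sigma_cp = sqrt(sigma_a^2 * sigma_v^2 / (sigma_a^2 + sigma_v^2))`, which
#' is always at most the smaller single-cue sigma.
#'
#' @param spec An `msi_fusion_spec`.
#' @return List with `mu_cp`, `sigma_cp`, `w_a`, `w_v`, class
#'   `msi_analytic_posterior`.
#' @export
#' @examples
#' analytic_posterior(fusion_spec(8, 5, 1, 2))
analytic_posterior <- function(spec) {
  stopifnot(inherits(spec, "msi_fusion_spec"))
  pa <- 1 / spec$sigma_a^2
  pv <- 1 / spec$sigma_v^2
  w_a <- pa / (pa + pv)
  w_v <- pv / (pa + pv)
  structure(list(mu_cp = spec$mu_a * w_a + spec$mu_v * w_v,
                 sigma_cp = sqrt(spec$sigma_a^2 * spec$sigma_v^2 /
                                   (spec$sigma_a^2 + spec$sigma_v^2)),
                 w_a = w_a, w_v = w_v),
            class = "msi_analytic_posterior")
}

# Normal draws truncated to [lo, hi] by seeded resampling.
draw_truncated_normal <- function(rng, k, mu, sigma, lo, hi) {
  x <- mu + sigma * stats::qnorm(rng(k))
  bad <- which(x < lo | x > hi)
  guard <- 0L
  while (length(bad) > 0L && guard < 1000L) {
    x[bad] <- mu + sigma * stats::qnorm(rng(length(bad)))
    bad <- which(x < lo | x > hi)
    guard <- guard + 1L
  }
  if (length(bad) > 0L) x[bad] <- pmin(pmax(x[bad], lo), hi)
  x
}

#' Run the stochastic cue-fusion experiment
#'
#' Draws `n_draws` pairs of auditory and visual stimulus locations from the
#' spec's distributions, presents each pair to the network (cortical fields
#' copying the sensory ones when `feedback` is on, zero otherwise), classifies
#' each response as fused (single peak) or separate, and collects the
#' maximum-likelihood location of the fused trials. The moments of those
#' locations form the network's empirical posterior, to be compared with
#' [analytic_posterior()].
#'
#' @param spec An `msi_fusion_spec`.
#' @param params An `msi_params` object.
#' @param feedback Logical: cortical feedback active?
#' @param intensity Stimulus intensity for both modalities, default 0.5.
#' @return An `msi_empirical_posterior`: `fused_locations`, `mean`, `std`,
#'   `fused_fraction`, `n_draws`, `feedback`, plus the per-draw table `draws`
#'   (audio/visual centers, fusion class, ML location).
#' @export
run_fusion_experiment <- function(spec, params = msi_params(),
                                  feedback = TRUE, intensity = 0.5) {
  stopifnot(inherits(spec, "msi_fusion_spec"))
  n <- params$n_neurons
  lo <- 0; hi <- n - 1
  rng_a <- rng_stream(spec$seed, 20L)
  rng_v <- rng_stream(spec$seed, 21L)
  centers_a <- draw_truncated_normal(rng_a, spec$n_draws, spec$mu_a,
                                     spec$sigma_a, lo, hi)
  centers_v <- draw_truncated_normal(rng_v, spec$n_draws, spec$mu_v,
                                     spec$sigma_v, lo, hi)
  inputs <- lapply(seq_len(spec$n_draws), function(k) {
    a <- gaussian_input(stimulus_spec(centers_a[k], spec$sigma_a, intensity), n)
    v <- gaussian_input(stimulus_spec(centers_v[k], spec$sigma_v, intensity), n)
    if (feedback) msi_inputs(a, v, a, v) else msi_inputs(a, v, numeric(n), numeric(n))
  })
  out <- simulate_batch(inputs, params)
  fusion_from_rates(out$sc_rate, centers_a, centers_v, feedback)
}

# Shared classification/summary step for fusion experiments.
fusion_from_rates <- function(sc_rate, centers_a, centers_v, feedback) {
  n_draws <- ncol(sc_rate)
  cls <- character(n_draws)
  loc <- rep(NA_real_, n_draws)
  for (k in seq_len(n_draws)) {
    pk <- find_peaks(sc_rate[, k])
    cls[k] <- classify_fusion(pk)
    if (cls[k] == "fused") loc[k] <- pk[1]
  }
  fused <- loc[!is.na(loc)]
  frac <- length(fused) / n_draws
  if (frac < 0.05) {
    warning("fused_fraction below 0.05; empirical moments are unreliable",
            call. = FALSE)
  }
  structure(list(
    fused_locations = fused,
    mean = if (length(fused) > 0) mean(fused) else NA_real_,
    std = if (length(fused) > 1) stats::sd(fused) else NA_real_,
    fused_fraction = frac,
    n_draws = n_draws,
    feedback = feedback,
    draws = data.frame(audio_center = centers_a, visual_center = centers_v,
                       fusion = cls, ml_location = loc)
  ), class = "msi_empirical_posterior")
}

#' @export
print.msi_empirical_posterior <- function(x, ...) {
  cat("<msi_empirical_posterior> ", x$n_draws, " draws, fused fraction ",
      signif(x$fused_fraction, 3), "; mean ", signif(x$mean, 4),
      ", sd ", signif(x$std, 4), " (feedback ",
      if (isTRUE(x$feedback)) "on" else "off", ")\n", sep = "")
  invisible(x)
}

#' Compare empirical and analytic posteriors
#'
#' Signed errors of the network's empirical fused posterior against the
#' analytic reliability-weighted combination: `mean_error = mean - mu_cp` and
#' `variance_error = std^2 - sigma_cp^2`.
#'
#' @param emp An `msi_empirical_posterior` with at least one fused trial.
#' @param ana An `msi_analytic_posterior`.
#' @return List with `mean_error` and `variance_error`.
#' @export
compare_posteriors <- function(emp, ana) {
  stopifnot(inherits(emp, "msi_empirical_posterior"),
            inherits(ana, "msi_analytic_posterior"))
  if (length(emp$fused_locations) == 0L) {
    stop("no fused trials: posterior comparison undefined", call. = FALSE)
  }
  list(mean_error = emp$mean - ana$mu_cp,
       variance_error = emp$std^2 - ana$sigma_cp^2)
}

#' Fusion probability as a function of spatial offset
#'
#' For each offset the auditory stimulus is fixed at `readout_loc` and the
#' visual stimulus at `readout_loc + offset` (channel units, equal to
#' multiples of `sigma_z` when `sigma_z = 1`); the fraction of trials whose
#' response shows a single peak is the fusion probability. With
#' `noise_level = 0` (default) the trial is deterministic and one run per
#' offset suffices; a positive `noise_level` jitters the intensities over
#' `per_offset_draws` seeded trials, giving graded fractions.
#'
#' @param params An `msi_params` object.
#' @param offsets Nonnegative spatial offsets in channel units.
#' @param per_offset_draws Trials per offset (used when `noise_level > 0`).
#' @param seed Integer seed.
#' @param noise_level Relative intensity jitter amplitude, default 0.
#' @param intensity Base stimulus intensity, default 0.5.
#' @param sigma_z Stimulus width, default 1.
#' @param readout_loc Auditory stimulus location, default 8.
#' @return Data frame with columns `offset`, `feedback`, `fused_probability`.
#' @export
run_fusion_vs_offset <- function(params = msi_params(),
                                 offsets = 0:6,
                                 per_offset_draws = 1L,
                                 seed = 1L,
                                 noise_level = 0,
                                 intensity = 0.5,
                                 sigma_z = 1,
                                 readout_loc = 8L) {
  stopifnot(all(offsets >= 0), per_offset_draws >= 1L)
  n <- params$n_neurons
  n_trials <- if (noise_level > 0) as.integer(per_offset_draws) else 1L
  rng <- rng_stream(seed, 30L)
  cells <- expand.grid(trial = seq_len(n_trials), offset = offsets,
                       feedback = c(TRUE, FALSE))
  jit <- function() {
    if (noise_level > 0) {
      pmax(intensity * (1 + noise_level * (rng(1) * 2 - 1)), 1e-3)
    } else intensity
  }
  inputs <- lapply(seq_len(nrow(cells)), function(k) {
    ia <- jit(); iv <- jit()
    a <- gaussian_input(stimulus_spec(readout_loc, sigma_z, ia), n)
    v <- gaussian_input(stimulus_spec(readout_loc + cells$offset[k], sigma_z, iv), n)
    if (cells$feedback[k]) msi_inputs(a, v, a, v)
    else msi_inputs(a, v, numeric(n), numeric(n))
  })
  out <- simulate_batch(inputs, params)
  fused <- vapply(seq_len(nrow(cells)), function(k) {
    classify_fusion(find_peaks(out$sc_rate[, k])) == "fused"
  }, logical(1))
  agg <- stats::aggregate(fused, by = list(offset = cells$offset,
                                           feedback = cells$feedback), FUN = mean)
  names(agg)[3] <- "fused_probability"
  agg[order(!agg$feedback, agg$offset), , drop = FALSE]
}

#' The standard (mu, sigma) specification grid of the fusion experiment
#'
#' Cartesian product of the auditory means \{8, 14.5\}, visual means \{5, 8\}
#' and per-modality sigmas \{0.5, 1, 2, 3\} spanning the published ranges.
#'
#' @param n_draws Draws per spec.
#' @param seed Master seed; each spec receives a distinct child seed.
#' @return List of `msi_fusion_spec` objects (64 by default).
#' @export
fusion_spec_grid <- function(n_draws = 200L, seed = 1L) {
  g <- expand.grid(mu_a = c(8, 14.5), mu_v = c(5, 8),
                   sigma_a = c(0.5, 1, 2, 3), sigma_v = c(0.5, 1, 2, 3))
  lapply(seq_len(nrow(g)), function(k) {
    fusion_spec(g$mu_a[k], g$mu_v[k], g$sigma_a[k], g$sigma_v[k],
                n_draws = n_draws, seed = child_seed(seed, 100L + k))
  })
}

#' Run the fusion experiment over a grid of specs
#'
#' Convenience wrapper running [run_fusion_experiment()] for every spec with
#' both feedback settings in one batched integration, returning a tidy
#' summary per (spec, feedback) cell.
#'
#' @param specs List of `msi_fusion_spec` (see [fusion_spec_grid()]).
#' @param params An `msi_params` object.
#' @param intensity Stimulus intensity, default 0.5.
#' @return Data frame with the spec parameters, feedback flag, analytic
#'   `mu_cp`/`sigma_cp`, empirical `mean`/`std`, `fused_fraction`,
#'   `mean_error` and `variance_error`.
#' @export
run_fusion_grid <- function(specs, params = msi_params(), intensity = 0.5) {
  rows <- lapply(specs, function(sp) {
    ana <- analytic_posterior(sp)
    do.call(rbind, lapply(c(TRUE, FALSE), function(fb) {
      emp <- suppressWarnings(run_fusion_experiment(sp, params, feedback = fb,
                                                    intensity = intensity))
      ok <- length(emp$fused_locations) > 1L
      data.frame(mu_a = sp$mu_a, mu_v = sp$mu_v,
                 sigma_a = sp$sigma_a, sigma_v = sp$sigma_v,
                 feedback = fb,
                 mu_cp = ana$mu_cp, sigma_cp = ana$sigma_cp,
                 emp_mean = emp$mean, emp_std = emp$std,
                 fused_fraction = emp$fused_fraction,
                 mean_error = if (ok) emp$mean - ana$mu_cp else NA_real_,
                 variance_error = if (ok) emp$std^2 - ana$sigma_cp^2 else NA_real_)
    }))
  })
  do.call(rbind, rows)
}
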